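## The three-branch segmentation model: a feature-aggregation
## encoder-decoder segmentation network (seg), an attention network on
## 4-channel input (att) and a shallow constraint network (cons).
## Built on the reverse-mode engine in engine.R; one image per forward.

## ---- layer constructors (parameters drawn from the current RNG) ----------

layer_conv <- function(k, cin, cout, stride = 1L, dilation = 1L,
                       deformable = FALSE) {
  ly <- list(k = k, cin = cin, cout = cout, stride = stride,
             dilation = dilation, deformable = deformable,
             w = ps_param(array(stats::rnorm(k * k * cin * cout, 0,
                                             sqrt(2 / (k * k * cin))),
                                c(k, k, cin, cout))),
             b = ps_param(numeric(cout)))
  if (deformable) {
    ## offset-predicting conv: zero-initialised so training starts from the
    ## regular sampling grid
    ly$ow <- ps_param(array(0, c(3, 3, cin, 2L * k * k)))
    ly$ob <- ps_param(numeric(2L * k * k))
  }
  ly
}

layer_bn <- function(C) {
  state <- new.env(parent = emptyenv())
  state$rm <- numeric(C); state$rv <- rep(1, C)
  class(state) <- "ps_bnstate"
  list(gamma = ps_param(rep(1, C)), beta = ps_param(numeric(C)),
       state = state)
}

layer_dense <- function(cin, cout) {
  list(w = ps_param(matrix(stats::rnorm(cin * cout, 0, sqrt(2 / cin)),
                           cin, cout)),
       b = ps_param(numeric(cout)))
}

pp <- function(ctx, p) if (ctx$training) nd_param(ctx, p) else p$v

fw_conv <- function(ctx, ly, x) {
  if (isTRUE(ly$deformable)) {
    off <- nd_conv2d(ctx, x, pp(ctx, ly$ow), pp(ctx, ly$ob),
                     stride = ly$stride, dilation = ly$dilation)
    nd_dconv2d(ctx, x, pp(ctx, ly$w), pp(ctx, ly$b), off,
               stride = ly$stride, dilation = ly$dilation)
  } else {
    nd_conv2d(ctx, x, pp(ctx, ly$w), pp(ctx, ly$b),
              stride = ly$stride, dilation = ly$dilation)
  }
}

fw_bn <- function(ctx, ly, x)
  nd_bn(ctx, x, pp(ctx, ly$gamma), pp(ctx, ly$beta), ly$state, ctx$training)

fw_dense <- function(ctx, ly, x) nd_dense(ctx, x, pp(ctx, ly$w), pp(ctx, ly$b))

## ---- residual block -------------------------------------------------------

layer_resblock <- function(cin, cout, stride = 1L, dilation = 1L,
                           deformable = FALSE) {
  list(conv1 = layer_conv(3L, cin, cout, stride, dilation, deformable),
       bn1 = layer_bn(cout),
       conv2 = layer_conv(3L, cout, cout, 1L, dilation, deformable),
       bn2 = layer_bn(cout),
       proj = if (stride != 1L || cin != cout)
         list(conv = layer_conv(1L, cin, cout, stride), bn = layer_bn(cout)))
}

fw_resblock <- function(ctx, blk, x) {
  h <- nd_relu(ctx, fw_bn(ctx, blk$bn1, fw_conv(ctx, blk$conv1, x)))
  h <- fw_bn(ctx, blk$bn2, fw_conv(ctx, blk$conv2, h))
  sc <- if (!is.null(blk$proj))
    fw_bn(ctx, blk$proj$bn, fw_conv(ctx, blk$proj$conv, x)) else x
  nd_relu(ctx, nd_add(ctx, h, sc))
}

## ---- CBAM ------------------------------------------------------------------

layer_cbam <- function(C, reduction = 2L) {
  hidden <- max(1L, C %/% reduction)
  list(mlp1 = layer_dense(C, hidden), mlp2 = layer_dense(hidden, C),
       spatial = layer_conv(7L, 2L, 1L))
}

#' @keywords internal
fw_cbam <- function(ctx, blk, x) {
  mlp <- function(v) fw_dense(ctx, blk$mlp2,
                              nd_relu(ctx, fw_dense(ctx, blk$mlp1, v)))
  cw <- nd_sigmoid(ctx, nd_add(ctx, mlp(nd_spatial_max(ctx, x)),
                               mlp(nd_spatial_mean(ctx, x))))
  x1 <- nd_scale_channels(ctx, x, cw)
  sm <- nd_sigmoid(ctx, fw_conv(ctx, blk$spatial,
                                nd_concat_c(ctx, nd_channel_max(ctx, x1),
                                            nd_channel_mean(ctx, x1))))
  nd_scale_spatial(ctx, x1, sm)
}

#' Convolutional block attention on a feature map
#'
#' Applies channel attention (sigmoid of a shared two-layer MLP over the
#' global max- and average-pooled channel descriptors, combined by
#' element-wise addition) followed by spatial attention (a 7x7 convolution
#' over the channel-wise max and mean maps), both multiplicatively. The
#' output has the shape of the input and is attenuated element-wise, since
#' every attention weight lies in (0, 1).
#'
#' @param features `H x W x C` feature array.
#' @param block a CBAM block from the internal constructor; a fresh one is
#'   drawn when omitted (useful for testing).
#' @param seed seed for the fresh block's parameters.
#' @return `H x W x C` array.
#' @export
cbam <- function(features, block = NULL, seed = 1L) {
  if (is.null(block))
    block <- with_seed(seed, layer_cbam(dim(features)[3]))
  fw_cbam(ctx_new(FALSE), block, features)
}

## ---- decoder block ---------------------------------------------------------

layer_decoder_block <- function(c_up, c_skip, c_out) {
  list(transform = layer_conv(1L, c_up, c_skip),
       conv1 = layer_conv(1L, c_skip, c_out), bn1 = layer_bn(c_out),
       conv2 = layer_conv(3L, c_out, c_out), bn2 = layer_bn(c_out),
       conv3 = layer_conv(1L, c_out, c_out))
}

fw_decoder_block <- function(ctx, blk, upper, skip) {
  tu <- fw_conv(ctx, blk$transform, upper)
  du <- dim(val(tu)); ds <- dim(val(skip))
  if (!identical(du, ds))
    stop(sprintf("decoder block: transformed upper features %s and skip features %s have incompatible shapes",
                 paste(du, collapse = "x"), paste(ds, collapse = "x")),
         call. = FALSE)
  h <- nd_add(ctx, tu, skip)
  h <- nd_relu(ctx, fw_bn(ctx, blk$bn1, fw_conv(ctx, blk$conv1, h)))
  h <- nd_relu(ctx, fw_bn(ctx, blk$bn2, fw_conv(ctx, blk$conv2, h)))
  fw_conv(ctx, blk$conv3, h)
}

#' Decoder block: 1x1 transform, skip addition, bottleneck stack
#'
#' The previous decoder output is passed through a 1x1 convolution to
#' match the skip connection's channels, merged with the same-shape
#' encoder feature map by element-wise addition, and refined by a
#' 1x1 / 3x3 / 1x1 convolution stack.
#'
#' @param upper_features upsampled features from the previous decoder level.
#' @param skip_features same-resolution encoder features.
#' @param block internal block; a fresh one is drawn when omitted.
#' @param seed seed for the fresh block.
#' @return feature array at the skip resolution.
#' @export
decoder_block <- function(upper_features, skip_features, block = NULL,
                          seed = 1L) {
  if (is.null(block))
    block <- with_seed(seed, layer_decoder_block(dim(upper_features)[3],
                                                 dim(skip_features)[3],
                                                 dim(skip_features)[3]))
  fw_decoder_block(ctx_new(FALSE), block, upper_features, skip_features)
}

## ---- configuration ---------------------------------------------------------

#' Network configuration
#'
#' Size-scalable configuration of the three networks. The `"full"` preset
#' uses a ResNet-50-scale segmentation encoder and a ResNet-18-scale
#' attention encoder; `"small"` and `"tiny"` shrink all widths so the
#' whole model trains on one CPU at desk scale. The last encoder block
#' always runs at dilation `dilation_last_block` with stride 1, giving an
#' output stride of 1/16.
#'
#' @param preset `"tiny"`, `"small"` or `"full"`.
#' @param width_multiplier multiplies every channel width (minimum 2).
#' @param use_deformable use deformable convolutions in the encoder
#'   stages (offset-predicting convolution + bilinear sampling).
#' @param dilation_last_block dilation rate of the final encoder block.
#' @param consnet_n number of output channels N of the constraint
#'   network's final convolution.
#' @return a `net_config` list.
#' @export
net_config <- function(preset = c("tiny", "small", "full"),
                       width_multiplier = 1,
                       use_deformable = FALSE,
                       dilation_last_block = 2L,
                       consnet_n = 3L) {
  preset <- match.arg(preset)
  if (width_multiplier <= 0) stop("width_multiplier must be > 0", call. = FALSE)
  if (dilation_last_block < 1) stop("dilation_last_block must be >= 1",
                                    call. = FALSE)
  base <- switch(preset,
    tiny  = list(seg = c(8, 16, 24, 32, 32),  att = c(8, 8, 16, 16, 16),
                 cons = 16L, agg = 16L),
    small = list(seg = c(16, 32, 48, 64, 64), att = c(8, 16, 24, 32, 32),
                 cons = 32L, agg = 24L),
    full  = list(seg = c(64, 256, 512, 1024, 2048),
                 att = c(64, 64, 128, 256, 512), cons = 32L, agg = 64L))
  wm <- function(x) pmax(2L, as.integer(round(x * width_multiplier)))
  structure(list(preset = preset,
                 width_multiplier = width_multiplier,
                 seg_channels = wm(base$seg),
                 att_channels = wm(base$att),
                 cons_channels = wm(base$cons),
                 agg_channels = wm(base$agg),
                 use_deformable = isTRUE(use_deformable),
                 dilation_last_block = as.integer(dilation_last_block),
                 consnet_n = as.integer(consnet_n)),
            class = "net_config")
}

## ---- encoder-decoder constructor (shared by seg and att) ------------------

build_encdec <- function(in_channels, ch, agg, dilation_last,
                         deformable = FALSE) {
  list(
    stem = layer_conv(3L, in_channels, ch[1], stride = 2L,
                      deformable = deformable),
    stem_bn = layer_bn(ch[1]),
    stage1 = layer_resblock(ch[1], ch[2], 2L, deformable = deformable),
    stage2 = layer_resblock(ch[2], ch[3], 2L, deformable = deformable),
    stage3 = layer_resblock(ch[3], ch[4], 2L, deformable = deformable),
    stage4 = layer_resblock(ch[4], ch[5], 1L, dilation = dilation_last,
                            deformable = deformable),
    db3 = layer_decoder_block(ch[5], ch[3], agg),
    db2 = layer_decoder_block(agg, ch[2], agg),
    db1 = layer_decoder_block(agg, ch[1], agg),
    cbam3 = layer_cbam(agg), cbam2 = layer_cbam(agg), cbam1 = layer_cbam(agg),
    head = layer_conv(1L, agg, 1L))
}

## pad H and W up to multiples of 16 by edge replication
pad_to_16 <- function(image) {
  H <- dim(image)[1]; W <- dim(image)[2]
  H2 <- 16L * ((H + 15L) %/% 16L); W2 <- 16L * ((W + 15L) %/% 16L)
  if (H2 == H && W2 == W) return(list(image = image, H = H, W = W))
  ri <- c(seq_len(H), rep(H, H2 - H)); ci <- c(seq_len(W), rep(W, W2 - W))
  list(image = image[ri, ci, , drop = FALSE], H = H, W = W)
}

## forward through the encoder-decoder; f_cons (optional) is added to the
## first residual stage's output. Returns the pre-crop H x W x 1 node.
fw_encdec <- function(ctx, net, x, f_cons = NULL) {
  H <- dim(val(x))[1]; W <- dim(val(x))[2]
  s0 <- nd_relu(ctx, fw_bn(ctx, net$stem_bn, fw_conv(ctx, net$stem, x))) # /2
  e1 <- fw_resblock(ctx, net$stage1, s0)                                 # /4
  if (!is.null(f_cons)) {
    de <- dim(val(e1)); df <- dim(val(f_cons))
    if (!identical(de, df))
      stop(sprintf("f_cons shape %s does not match encoder-1 output shape %s",
                   paste(df, collapse = "x"), paste(de, collapse = "x")),
           call. = FALSE)
    e1 <- nd_add(ctx, e1, f_cons)
  }
  e2 <- fw_resblock(ctx, net$stage2, e1)                                 # /8
  e3 <- fw_resblock(ctx, net$stage3, e2)                                 # /16
  e4 <- fw_resblock(ctx, net$stage4, e3)                                 # /16
  d3 <- fw_decoder_block(ctx, net$db3,
                         nd_resize(ctx, e4, H %/% 8L, W %/% 8L), e2)
  d2 <- fw_decoder_block(ctx, net$db2,
                         nd_resize(ctx, d3, H %/% 4L, W %/% 4L), e1)
  d1 <- fw_decoder_block(ctx, net$db1,
                         nd_resize(ctx, d2, H %/% 2L, W %/% 2L), s0)
  a3 <- nd_resize(ctx, fw_cbam(ctx, net$cbam3, d3), H %/% 2L, W %/% 2L)
  a2 <- nd_resize(ctx, fw_cbam(ctx, net$cbam2, d2), H %/% 2L, W %/% 2L)
  a1 <- fw_cbam(ctx, net$cbam1, d1)
  agg <- nd_add(ctx, nd_add(ctx, a3, a2), a1)
  up <- nd_resize(ctx, agg, H, W)
  nd_sigmoid(ctx, fw_conv(ctx, net$head, up))
}

## ---- public model constructors & forwards ---------------------------------

#' Construct the segmentation network
#'
#' Residual encoder (stem + four stages, the last dilated at stride 1 for
#' an output stride of 1/16, optionally with deformable convolutions per
#' encoding layer), efficient decoder blocks, and a feature-aggregation
#' head: the three decoder outputs pass through CBAM blocks, are summed
#' element-wise, upsampled bilinearly and squashed to a single foreground
#' probability channel.
#'
#' @param config a [net_config()].
#' @param seed seed for weight initialisation.
#' @return a model object (list of layers) of class `seg_net`.
#' @export
seg_net <- function(config = net_config(), seed = 1L) {
  net <- with_seed(seed, build_encdec(3L, config$seg_channels,
                                      config$agg_channels,
                                      config$dilation_last_block,
                                      config$use_deformable))
  structure(c(net, list(config = config)), class = "seg_net")
}

#' Forward pass of the segmentation network
#'
#' @param model a [seg_net()].
#' @param image `H x W x 3` array in `[0, 1]`; sizes not divisible by 16
#'   are padded internally and the output is cropped back.
#' @param f_cons optional constraint feature map matching the first
#'   encoder stage's output shape (merged by element-wise addition).
#' @param ctx internal autodiff context; when `NULL` (eval mode) a plain
#'   `H x W` probability matrix in `[0, 1]` is returned.
#' @return probability map (`H x W` matrix), or a tape node when `ctx` is
#'   a training context.
#' @export
segnet_forward <- function(model, image, f_cons = NULL, ctx = NULL) {
  eval_mode <- is.null(ctx)
  if (eval_mode) ctx <- ctx_new(FALSE)
  pd <- pad_to_16(image)
  out <- fw_encdec(ctx, model, pd$image, f_cons)
  if (eval_mode) return(matrix(val(out)[seq_len(pd$H), seq_len(pd$W), 1],
                               pd$H, pd$W))
  out
}

#' Construct the attention network
#'
#' Same encoder-decoder/aggregation design as [seg_net()] with a smaller
#' encoder, taking a 4-channel input: RGB plus the binary superpixel
#' label plane.
#'
#' @inheritParams seg_net
#' @return a model object of class `att_net`.
#' @export
att_net <- function(config = net_config(), seed = 2L) {
  net <- with_seed(seed, build_encdec(4L, config$att_channels,
                                      config$agg_channels,
                                      config$dilation_last_block,
                                      config$use_deformable))
  structure(c(net, list(config = config)), class = "att_net")
}

#' Forward pass of the attention network
#'
#' @param model an [att_net()].
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param superpixel_label binary `H x W` matrix (0/1; the unlabeled code
#'   255 is rejected).
#' @param ctx internal autodiff context (see [segnet_forward()]).
#' @return attention map (`H x W` matrix in `[0, 1]`), or a tape node.
#' @export
attnet_forward <- function(model, image, superpixel_label, ctx = NULL) {
  if (any(superpixel_label == LABEL_UNL))
    stop("superpixel label contains the unlabeled code 255; it must be binary",
         call. = FALSE)
  if (!all(superpixel_label %in% c(0L, 1L)))
    stop("superpixel label must be binary 0/1", call. = FALSE)
  eval_mode <- is.null(ctx)
  if (eval_mode) ctx <- ctx_new(FALSE)
  x4 <- array(c(image, superpixel_label), c(dim(image)[1], dim(image)[2], 4L))
  pd <- pad_to_16(x4)
  out <- fw_encdec(ctx, model, pd$image)
  if (eval_mode) return(matrix(val(out)[seq_len(pd$H), seq_len(pd$W), 1],
                               pd$H, pd$W))
  out
}

#' Construct the constraint network
#'
#' A shallow CNN preserving low-level texture: conv1 and conv2 (3x3,
#' BatchNorm + ReLU, conv2 at stride 2) learn local details; a branch
#' through conv3 projects to the segmentation encoder's first-stage
#' channel count at stride 4, producing the constraint feature map
#' `f_cons`; the main branch is upsampled back to full resolution and
#' passed through conv4 and conv5, giving an N-channel output `h`.
#'
#' @param config a [net_config()].
#' @param seed seed for weight initialisation.
#' @return a model object of class `cons_net`.
#' @export
cons_net <- function(config = net_config(), seed = 3L) {
  cw <- config$cons_channels
  enc1 <- config$seg_channels[2]
  net <- with_seed(seed, list(
    conv1 = layer_conv(3L, 3L, cw), bn1 = layer_bn(cw),
    conv2 = layer_conv(3L, cw, cw, stride = 2L), bn2 = layer_bn(cw),
    conv3 = layer_conv(3L, cw, enc1),
    conv4 = layer_conv(3L, cw, cw), bn4 = layer_bn(cw),
    conv5 = layer_conv(3L, cw, config$consnet_n)))
  structure(c(net, list(config = config)), class = "cons_net")
}

#' Forward pass of the constraint network
#'
#' @param model a [cons_net()].
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param ctx internal autodiff context.
#' @return list with `f_cons` (feature map at the segmentation encoder's
#'   first-stage shape) and `h` (N-channel full-resolution map in `[0,1]`);
#'   plain arrays in eval mode, tape nodes in a training context.
#' @export
consnet_forward <- function(model, image, ctx = NULL) {
  if (is.null(ctx)) ctx <- ctx_new(FALSE)
  pd <- pad_to_16(image)
  H <- dim(pd$image)[1]; W <- dim(pd$image)[2]
  h1 <- nd_relu(ctx, fw_bn(ctx, model$bn1, fw_conv(ctx, model$conv1, pd$image)))
  h2 <- nd_relu(ctx, fw_bn(ctx, model$bn2, fw_conv(ctx, model$conv2, h1)))
  f_cons <- fw_conv(ctx, model$conv3, nd_avgpool2(ctx, h2))       # stride 4
  up <- nd_resize(ctx, h2, H, W)
  h4 <- nd_relu(ctx, fw_bn(ctx, model$bn4, fw_conv(ctx, model$conv4, up)))
  h <- nd_sigmoid(ctx, fw_conv(ctx, model$conv5, h4))
  list(f_cons = f_cons, h = h)
}

## ---- checkpointing ---------------------------------------------------------

collect_bn_states <- function(x) {
  if (inherits(x, "ps_bnstate")) return(list(x))
  if (is.list(x)) return(do.call(c, lapply(unname(x), collect_bn_states)))
  list()
}

#' Save and load model checkpoints
#'
#' Checkpoints store all parameter arrays, BatchNorm running statistics
#' and the network configuration; loading rebuilds the model from the
#' embedded config and restores the values.
#'
#' @param model a `joint_model` (see [joint_model()]) or a single network.
#' @param path file path (`.rds`).
#' @return `load_checkpoint` returns the restored model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(kind = class(model)[1],
               config = model$config,
               seeds = attr(model, "seeds"),
               params = lapply(collect_params(model), function(p) p$v),
               bn = lapply(collect_bn_states(model),
                           function(s) list(rm = s$rm, rv = s$rv))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- switch(ck$kind,
    seg_net = seg_net(ck$config, seed = 0L),
    att_net = att_net(ck$config, seed = 0L),
    cons_net = cons_net(ck$config, seed = 0L),
    joint_model = joint_model(ck$config, seeds = ck$seeds %||% c(1L, 2L, 3L)),
    stop(sprintf("unknown checkpoint kind '%s'", ck$kind), call. = FALSE))
  ps <- collect_params(model)
  stopifnot(length(ps) == length(ck$params))
  for (i in seq_along(ps)) ps[[i]]$v <- ck$params[[i]]
  ss <- collect_bn_states(model)
  stopifnot(length(ss) == length(ck$bn))
  for (i in seq_along(ss)) { ss[[i]]$rm <- ck$bn[[i]]$rm; ss[[i]]$rv <- ck$bn[[i]]$rv }
  model
}

#' Bundle the three networks into one trainable model
#'
#' @param config a [net_config()].
#' @param seeds integer vector of three initialisation seeds
#'   (segmentation, attention, constraint).
#' @return an object of class `joint_model`.
#' @export
joint_model <- function(config = net_config(), seeds = c(1L, 2L, 3L)) {
  m <- structure(list(seg = seg_net(config, seeds[1]),
                      att = att_net(config, seeds[2]),
                      cons = cons_net(config, seeds[3]),
                      config = config),
                 class = "joint_model")
  attr(m, "seeds") <- seeds
  m
}

#' Predict a foreground probability map
#'
#' Runs the constraint network to obtain `f_cons`, then the segmentation
#' network, in eval mode.
#'
#' @param model a `joint_model`, `seg_net`, or checkpoint path.
#' @param image `H x W x 3` array in `[0, 1]`.
#' @return `H x W` matrix of foreground probabilities.
#' @export
predict_mask <- function(model, image) {
  model <- load_model_maybe(model)
  if (inherits(model, "joint_model")) {
    fc <- consnet_forward(model$cons, image)$f_cons
    segnet_forward(model$seg, image, f_cons = fc)
  } else if (inherits(model, "seg_net")) {
    segnet_forward(model, image)
  } else stop("predict_mask needs a joint_model or seg_net", call. = FALSE)
}

load_model_maybe <- function(model) {
  if (is.character(model)) load_checkpoint(model) else model
}
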