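#' Loss weights for joint training
#'
#' `alpha` balances positive against negative Voronoi pixels inside the
#' attention loss; `beta`, `gamma`, `delta` weight the segmentation,
#' attention and constraint losses in the total objective. Defaults are
#' (0.4, 0.8, 1, 0.4), the setting used throughout the pipeline.
#'
#' @param alpha,beta,gamma,delta non-negative reals.
#' @return a `loss_weights` list.
#' @export
loss_weights <- function(alpha = 0.4, beta = 0.8, gamma = 1, delta = 0.4) {
  w <- list(alpha = alpha, beta = beta, gamma = gamma, delta = delta)
  if (any(unlist(w) < 0)) stop("loss weights must be >= 0", call. = FALSE)
  structure(w, class = "loss_weights")
}

## channel slice as a differentiable op (used by the constraint loss)
nd_channel_slice <- function(ctx, x, n) {
  xv <- val(x)
  op_record(ctx, list(x), xv[, , n, drop = FALSE], function(g) {
    dx <- array(0, dim(xv)); dx[, , n] <- g; list(dx)
  })
}

## coerce probability-map-like inputs (matrix or H x W x 1 array) to H x W x 1
as_map3 <- function(x) {
  if (is_node(x)) return(x)
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

#' Attention-masked segmentation loss
#'
#' Mean binary cross-entropy between the attention-masked prediction
#' `pred * f_att` and the binary superpixel label, over all pixels.
#' Probabilities are clamped to `[eps, 1 - eps]`. The attention map is a
#' fixed weighting inside this loss (it is trained by [att_loss()]), so
#' pass a plain array for `f_att` unless deliberately training jointly.
#'
#' @param pred foreground probability map (`H x W` matrix, `H x W x 1`
#'   array, or a tape node during training).
#' @param f_att attention map with the same spatial shape.
#' @param y_s binary superpixel label matrix (the unlabeled code 255 is
#'   rejected).
#' @param eps clamping constant for the log terms.
#' @param ctx internal autodiff context.
#' @return scalar loss (numeric, or a tape node during training).
#' @export
seg_loss <- function(pred, f_att, y_s, eps = 1e-7, ctx = NULL) {
  if (any(y_s == LABEL_UNL))
    stop("y_s contains the unlabeled code 255; the superpixel label is binary",
         call. = FALSE)
  if (is.null(ctx)) ctx <- ctx_new(FALSE)
  pred <- as_map3(pred); f_att <- as_map3(f_att)
  y <- array(as.numeric(y_s), dim(val(pred)))
  q <- nd_clamp(ctx, nd_mul(ctx, pred, f_att), eps, 1 - eps)
  ce <- nd_add(ctx,
               nd_mul(ctx, y, nd_log(ctx, q)),
               nd_mul(ctx, 1 - y,
                      nd_log(ctx, nd_sub(ctx, array(1, dim(y)), q))))
  nd_mul(ctx, nd_mean(ctx, ce), -1)
}

#' Partial attention loss on Voronoi labels
#'
#' The attention map is pushed towards 1 on both the positive (dilated
#' point) and the negative (Voronoi ridge) pixels, with the negative term
#' weighted by `alpha`:
#' `sum_{p in y_v+} |1 - f_att(p)| / |y_v+| + alpha * sum_{p in y_v-} |1 - f_att(p)| / |y_v-|`.
#' Both confidently-nucleus and confidently-background pixels therefore
#' target 1, marking the mask as a "confident region" map that blanks out
#' only the noisy boundary band (which stays unsupervised and is free to
#' fall to 0). Set `neg_target = 0` for the alternative reading in which
#' ridge pixels are pushed towards 0. Unlabeled pixels contribute nothing.
#'
#' @param f_att attention map (`H x W` matrix or tape node).
#' @param y_v tri-state Voronoi label: a coded matrix or a
#'   `voronoi_label` object. Must contain at least one positive and one
#'   negative pixel.
#' @param alpha non-negative weight of the negative term.
#' @param neg_target 1 (as printed) or 0.
#' @param ctx internal autodiff context.
#' @return scalar loss (numeric, or a tape node during training).
#' @export
att_loss <- function(f_att, y_v, alpha = 0.4, neg_target = 1, ctx = NULL) {
  if (inherits(y_v, "voronoi_label")) y_v <- y_v$label
  if (is.null(ctx)) ctx <- ctx_new(FALSE)
  f_att <- as_map3(f_att)
  d <- dim(val(f_att))
  pos <- array(as.numeric(y_v == LABEL_POS), d)
  neg <- array(as.numeric(y_v == LABEL_NEG), d)
  npos <- sum(pos); nneg <- sum(neg)
  if (npos == 0) stop("y_v has no positive pixels", call. = FALSE)
  if (nneg == 0) stop("y_v has no negative pixels", call. = FALSE)
  dev_pos <- nd_abs(ctx, nd_sub(ctx, array(1, d), f_att))
  dev_neg <- if (neg_target == 1) dev_pos else nd_abs(ctx, f_att)
  pterm <- nd_mul(ctx, nd_sum(ctx, nd_mul(ctx, pos, dev_pos)), 1 / npos)
  nterm <- nd_mul(ctx, nd_sum(ctx, nd_mul(ctx, neg, dev_neg)), alpha / nneg)
  nd_add(ctx, pterm, nterm)
}

#' Constraint loss: mean L1 against the segmentation output
#'
#' `(1/N) * sum_n mean |f_I - h_n|`, the channel-averaged L1 distance
#' between the segmentation probability map and each channel of the
#' constraint network's output. The segmentation output is the (fixed)
#' supervision signal inside this loss, so pass it as a plain array
#' unless deliberately training jointly.
#'
#' @param f_I segmentation probability map (`H x W` matrix or array).
#' @param h `H x W x N` constraint network output (array or tape node).
#' @param ctx internal autodiff context.
#' @return scalar loss (numeric, or a tape node during training).
#' @export
cons_loss <- function(f_I, h, ctx = NULL) {
  if (is.null(ctx)) ctx <- ctx_new(FALSE)
  N <- dim(val(h))[3]
  if (is.null(N) || N == 0) stop("h must have at least one channel", call. = FALSE)
  f <- val(as_map3(f_I))
  total <- NULL
  for (n in seq_len(N)) {
    term <- nd_mean(ctx, nd_abs(ctx, nd_sub(ctx, nd_channel_slice(ctx, h, n), f)))
    total <- if (is.null(total)) term else nd_add(ctx, total, term)
  }
  nd_mul(ctx, total, 1 / N)
}

#' Total training objective
#'
#' `beta * L_seg + gamma * L_att + delta * L_cons`.
#'
#' @param L_seg,L_att,L_cons scalar losses (numeric or tape nodes).
#' @param w a [loss_weights()].
#' @param ctx internal autodiff context.
#' @return scalar loss (numeric, or a tape node during training).
#' @export
total_loss <- function(L_seg, L_att, L_cons, w = loss_weights(), ctx = NULL) {
  stopifnot(is.finite(val(L_seg)), is.finite(val(L_att)), is.finite(val(L_cons)))
  if (is.null(ctx)) ctx <- ctx_new(FALSE)
  nd_add(ctx, nd_add(ctx, nd_mul(ctx, L_seg, w$beta),
                     nd_mul(ctx, L_att, w$gamma)),
         nd_mul(ctx, L_cons, w$delta))
}
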