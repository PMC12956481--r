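#' Training configuration
#'
#' Defaults: Adam with learning rate 0.001
#' and weight decay 0.0005, 60 epochs, batch size 1, learning rate halved
#' when the validation total loss has not decreased within 4 epochs,
#' loss weights (alpha, beta, gamma, delta) = (0.4, 0.8, 1, 0.4). Desk
#' scale profiles should override `epochs` and the network widths only.
#'
#' @param lr initial learning rate (> 0).
#' @param weight_decay L2 weight decay added to the gradients.
#' @param epochs number of training epochs (>= 1).
#' @param batch_size images per optimiser step.
#' @param plateau_patience_epochs epochs without validation improvement
#'   before the learning rate is halved.
#' @param lr_halving_factor multiplicative factor at each plateau (0.5).
#' @param loss_weights a [loss_weights()].
#' @param net a [net_config()].
#' @param augmentation augmentation config list (see [augment()]) or
#'   `NULL` to disable.
#' @param seed master seed: controls weight init, the validation split,
#'   shuffling and augmentation draws.
#' @param val_fraction fraction of images held out for validation
#'   (strictly between 0 and 1).
#' @param detach keep the attention map fixed inside the segmentation
#'   loss and the segmentation output fixed inside the constraint loss
#'   (so each branch is trained only by its own objective); set `FALSE`
#'   to restore fully joint gradients for ablation.
#' @param att_neg_target target of the attention loss on ridge pixels
#'   (1 as printed, 0 for the alternative reading; see [att_loss()]).
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 0.001, weight_decay = 0.0005, epochs = 60L,
                         batch_size = 1L, plateau_patience_epochs = 4L,
                         lr_halving_factor = 0.5,
                         loss_weights = pointseg::loss_weights(),
                         net = net_config(),
                         augmentation = list(hflip = 0.5, vflip = 0.5),
                         seed = 1L, val_fraction = 0.2,
                         detach = TRUE, att_neg_target = 1) {
  if (lr <= 0) stop("lr must be > 0", call. = FALSE)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("val_fraction must be strictly between 0 and 1", call. = FALSE)
  structure(list(lr = lr, weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 plateau_patience_epochs = as.integer(plateau_patience_epochs),
                 lr_halving_factor = lr_halving_factor,
                 loss_weights = loss_weights, net = net,
                 augmentation = augmentation, seed = as.integer(seed),
                 val_fraction = val_fraction, detach = isTRUE(detach),
                 att_neg_target = att_neg_target),
            class = "train_config")
}

#' Plateau learning-rate scheduler
#'
#' Stateful reduce-on-plateau rule: the learning rate is multiplied by
#' `factor` whenever the monitored loss has not decreased for `patience`
#' consecutive updates.
#'
#' @param lr initial learning rate.
#' @param patience updates without improvement before a drop.
#' @param factor multiplicative factor (0.5 halves the rate).
#' @return an environment with `$update(val)` (returns the current lr
#'   after seeing validation loss `val`) and `$lr`.
#' @export
plateau_scheduler <- function(lr, patience = 4L, factor = 0.5) {
  st <- new.env(parent = emptyenv())
  st$lr <- lr; st$best <- Inf; st$wait <- 0L
  st$update <- function(val) {
    if (val < st$best - 1e-12) {
      st$best <- val
      st$wait <- 0L
    } else {
      st$wait <- st$wait + 1L
      if (st$wait >= patience) {
        st$lr <- st$lr * factor
        st$wait <- 0L
      }
    }
    st$lr
  }
  st
}

## pad a label map to multiples of 16 by edge replication; for tri-state
## maps the padded band is set to unlabeled so it contributes no loss
pad_label16 <- function(m, tri_state = FALSE) {
  H <- nrow(m); W <- ncol(m)
  H2 <- 16L * ((H + 15L) %/% 16L); W2 <- 16L * ((W + 15L) %/% 16L)
  if (H2 == H && W2 == W) return(m)
  out <- m[c(seq_len(H), rep(H, H2 - H)), c(seq_len(W), rep(W, W2 - W))]
  if (tri_state) {
    if (H2 > H) out[(H + 1):H2, ] <- LABEL_UNL
    if (W2 > W) out[, (W + 1):W2] <- LABEL_UNL
  }
  out
}

## one weakly supervised training step (forward + backward); returns the
## loss components. Gradients accumulate in the model's parameters.
weak_step <- function(model, img, yv_m, ys_m, cfg, training = TRUE) {
  ctx <- ctx_new(training)
  w <- cfg$loss_weights
  cons <- consnet_forward(model$cons, img, ctx = ctx)
  fc_in <- if (cfg$detach) nd_detach(cons$f_cons) else cons$f_cons
  pred <- segnet_forward(model$seg, img, f_cons = fc_in, ctx = ctx)
  fatt <- attnet_forward(model$att, img, pad_label16(ys_m), ctx = ctx)
  ys_p <- pad_label16(ys_m)
  yv_p <- pad_label16(yv_m, tri_state = TRUE)
  fatt_fixed <- if (cfg$detach) nd_detach(fatt) else fatt
  L_seg <- seg_loss(pred, fatt_fixed, ys_p, ctx = ctx)
  L_att <- att_loss(fatt, yv_p, alpha = w$alpha,
                    neg_target = cfg$att_neg_target, ctx = ctx)
  pred_fixed <- if (cfg$detach) nd_detach(pred) else pred
  L_cons <- cons_loss(pred_fixed, cons$h, ctx = ctx)
  L_tot <- total_loss(L_seg, L_att, L_cons, w, ctx = ctx)
  if (training) backward(ctx, L_tot)
  c(total = val(L_tot), seg = val(L_seg), att = val(L_att),
    cons = val(L_cons))
}

## shared two-branch-label training loop; `data` is a named list of
## list(image, yv, ys) entries
train_core <- function(data, cfg, stage, run_dir = NULL) {
  ids <- names(data)
  n <- length(ids)
  model <- with_seed(cfg$seed,
                     joint_model(cfg$net, seeds = derive_seeds(cfg$seed, 3L)))
  params <- collect_params(model)
  zero_grads(params)

  val_n <- max(1L, floor(cfg$val_fraction * n))
  val_ids <- with_seed(cfg$seed + 1L, sample(ids, val_n))
  train_ids <- setdiff(ids, val_ids)
  if (!length(train_ids)) stop("no training images left after the validation split",
                               call. = FALSE)
  sched <- plateau_scheduler(cfg$lr, cfg$plateau_patience_epochs,
                             cfg$lr_halving_factor)
  aug_seeds <- derive_seeds(cfg$seed + 2L, cfg$epochs * length(train_ids))
  shuf_seeds <- derive_seeds(cfg$seed + 3L, cfg$epochs)

  rec <- vector("list", cfg$epochs)
  best_val <- Inf; best_params <- NULL; best_bn <- NULL
  bns <- collect_bn_states(model)
  t_step <- 0L
  for (ep in seq_len(cfg$epochs)) {
    lr_now <- sched$lr
    order_ids <- with_seed(shuf_seeds[ep], sample(train_ids))
    comp <- matrix(0, length(order_ids), 4L)
    in_batch <- 0L
    for (i in seq_along(order_ids)) {
      d <- data[[order_ids[i]]]
      img <- d$image; yv_m <- d$yv; ys_m <- d$ys
      if (!is.null(cfg$augmentation) && length(cfg$augmentation)) {
        a <- augment(img, list(yv_m, ys_m), NULL, cfg$augmentation,
                     seed = aug_seeds[(ep - 1L) * length(train_ids) + i])
        ## keep the original labels if augmentation removed either
        ## supervision set (the attention loss needs both)
        if (any(a$label_maps[[1]] == LABEL_POS) &&
            any(a$label_maps[[1]] == LABEL_NEG) &&
            any(a$label_maps[[2]] == LABEL_POS)) {
          img <- a$image; yv_m <- a$label_maps[[1]]; ys_m <- a$label_maps[[2]]
        }
      }
      comp[i, ] <- weak_step(model, img, yv_m, ys_m, cfg, training = TRUE)
      in_batch <- in_batch + 1L
      if (in_batch >= cfg$batch_size || i == length(order_ids)) {
        if (in_batch > 1L) for (p in params) p$g <- p$g / in_batch
        t_step <- t_step + 1L
        adam_step(params, lr_now, t_step, weight_decay = cfg$weight_decay)
        in_batch <- 0L
      }
    }
    val_tot <- mean(vapply(val_ids, function(id) {
      d <- data[[id]]
      weak_step(model, d$image, d$yv, d$ys, cfg, training = FALSE)[["total"]]
    }, 1))
    if (val_tot < best_val) {
      best_val <- val_tot
      best_params <- lapply(params, function(p) p$v)
      best_bn <- lapply(bns, function(s) list(rm = s$rm, rv = s$rv))
    }
    sched$update(val_tot)
    rec[[ep]] <- data.frame(epoch = ep, stage = stage,
                            train_total = mean(comp[, 1]),
                            train_seg = mean(comp[, 2]),
                            train_att = mean(comp[, 3]),
                            train_cons = mean(comp[, 4]),
                            val_total = val_tot, lr = lr_now)
  }
  ## restore the best-validation weights
  for (i in seq_along(params)) params[[i]]$v <- best_params[[i]]
  for (i in seq_along(bns)) {
    bns[[i]]$rm <- best_bn[[i]]$rm; bns[[i]]$rv <- best_bn[[i]]$rv
  }
  record <- do.call(rbind, rec)
  class(record) <- c("run_record", "data.frame")
  ckpt <- NULL
  if (!is.null(run_dir)) {
    dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
    ckpt <- file.path(run_dir, "checkpoint.rds")
    save_checkpoint(model, ckpt)
    utils::write.csv(record, file.path(run_dir, "run_record.csv"),
                     row.names = FALSE)
  }
  list(model = model, record = record, checkpoint = ckpt,
       val_ids = val_ids)
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("<run_record: stage %s, %d epochs>\n", x$stage[1], nrow(x)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

## read images + labels for the training entry points
load_training_data <- function(dataset_dir, ys_paths, pseudolabels_dir) {
  ids <- dataset_ids(dataset_dir)
  data <- list()
  for (id in ids) {
    yv_f <- file.path(pseudolabels_dir, paste0(id, "_voronoi.png"))
    ys_f <- ys_paths(id)
    if (!file.exists(yv_f))
      stop(sprintf("missing Voronoi pseudo-label for image '%s' (%s)", id, yv_f),
           call. = FALSE)
    if (!file.exists(ys_f))
      stop(sprintf("missing superpixel label for image '%s' (%s)", id, ys_f),
           call. = FALSE)
    data[[id]] <- list(
      image = read_image(file.path(dataset_dir, "images", paste0(id, ".png"))),
      yv = read_label(yv_f),
      ys = read_label(ys_f))
  }
  data
}

#' Stage-1 training on Voronoi and superpixel pseudo-labels
#'
#' Jointly trains the segmentation, attention and constraint networks on
#' the pseudo-labels with the total objective, Adam, and the plateau
#' learning-rate schedule; the checkpoint with the best validation loss
#' is retained.
#'
#' @param dataset_dir dataset in the standard layout.
#' @param config a [train_config()].
#' @param pseudolabels_dir directory with `<id>_voronoi.png` and
#'   `<id>_superpixel.png` (default `<dataset_dir>/pseudolabels`).
#' @param run_dir optional output directory for `checkpoint.rds` and
#'   `run_record.csv`.
#' @return list with `model` (a `joint_model`), `record` (a `run_record`
#'   data frame with per-epoch train/val losses and the lr trace),
#'   `checkpoint` (path or `NULL`) and `val_ids`.
#' @export
train_stage1 <- function(dataset_dir, config = train_config(),
                         pseudolabels_dir = file.path(dataset_dir, "pseudolabels"),
                         run_dir = NULL) {
  data <- load_training_data(dataset_dir,
    function(id) file.path(pseudolabels_dir, paste0(id, "_superpixel.png")),
    pseudolabels_dir)
  train_core(data, config, stage = 1L, run_dir = run_dir)
}

#' Stage-2 retraining on confident-learning refined labels
#'
#' Identical to [train_stage1()] with the refined superpixel labels
#' `y_re` replacing `y_s` everywhere, including the attention network's
#' fourth input channel. Voronoi labels are unchanged.
#'
#' @param dataset_dir dataset in the standard layout.
#' @param refined_labels_dir directory with `<id>_refined.png`.
#' @param config a [train_config()].
#' @param pseudolabels_dir directory with the (unchanged) Voronoi labels.
#' @param run_dir optional output directory.
#' @return as [train_stage1()].
#' @export
train_stage2 <- function(dataset_dir, refined_labels_dir,
                         config = train_config(),
                         pseudolabels_dir = file.path(dataset_dir, "pseudolabels"),
                         run_dir = NULL) {
  data <- load_training_data(dataset_dir,
    function(id) file.path(refined_labels_dir, paste0(id, "_refined.png")),
    pseudolabels_dir)
  train_core(data, config, stage = 2L, run_dir = run_dir)
}

#' Fully supervised baseline on ground-truth masks
#'
#' Trains the plain segmentation encoder-decoder (no attention or
#' constraint branch, no feature merge) with binary cross-entropy against
#' the dense ground-truth masks. Kept as a reference ceiling for the
#' weakly supervised pipeline.
#'
#' @param dataset_dir dataset in the standard layout (needs `masks/`).
#' @param config a [train_config()].
#' @param run_dir optional output directory.
#' @return list with `model` (a `seg_net`), `record` and `checkpoint`.
#' @export
train_supervised <- function(dataset_dir, config = train_config(),
                             run_dir = NULL) {
  ids <- dataset_ids(dataset_dir)
  data <- list()
  for (id in ids) {
    data[[id]] <- list(
      image = read_image(file.path(dataset_dir, "images", paste0(id, ".png"))),
      gt = read_mask(file.path(dataset_dir, "masks", paste0(id, ".png"))))
  }
  cfg <- config
  model <- with_seed(cfg$seed, seg_net(cfg$net, seed = derive_seeds(cfg$seed, 1L)))
  params <- collect_params(model)
  zero_grads(params)
  n <- length(ids)
  val_ids <- with_seed(cfg$seed + 1L, sample(ids, max(1L, floor(cfg$val_fraction * n))))
  train_ids <- setdiff(ids, val_ids)
  sched <- plateau_scheduler(cfg$lr, cfg$plateau_patience_epochs,
                             cfg$lr_halving_factor)
  shuf_seeds <- derive_seeds(cfg$seed + 3L, cfg$epochs)
  sup_step <- function(img, gt, training) {
    ctx <- ctx_new(training)
    pred <- segnet_forward(model, img, ctx = ctx)
    ones <- array(1, dim(val(pred)))
    L <- seg_loss(pred, ones, pad_label16(gt), ctx = ctx)
    if (training) backward(ctx, L)
    val(L)
  }
  rec <- vector("list", cfg$epochs)
  best_val <- Inf; best_params <- NULL
  t_step <- 0L
  for (ep in seq_len(cfg$epochs)) {
    lr_now <- sched$lr
    order_ids <- with_seed(shuf_seeds[ep], sample(train_ids))
    tr <- numeric(length(order_ids))
    for (i in seq_along(order_ids)) {
      d <- data[[order_ids[i]]]
      tr[i] <- sup_step(d$image, d$gt, TRUE)
      t_step <- t_step + 1L
      adam_step(params, lr_now, t_step, weight_decay = cfg$weight_decay)
    }
    val_tot <- mean(vapply(val_ids,
      function(id) sup_step(data[[id]]$image, data[[id]]$gt, FALSE), 1))
    if (val_tot < best_val) {
      best_val <- val_tot
      best_params <- lapply(params, function(p) p$v)
    }
    sched$update(val_tot)
    rec[[ep]] <- data.frame(epoch = ep, stage = 0L, train_total = mean(tr),
                            val_total = val_tot, lr = lr_now)
  }
  for (i in seq_along(params)) params[[i]]$v <- best_params[[i]]
  record <- do.call(rbind, rec)
  class(record) <- c("run_record", "data.frame")
  ckpt <- NULL
  if (!is.null(run_dir)) {
    dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
    ckpt <- file.path(run_dir, "checkpoint.rds")
    save_checkpoint(model, ckpt)
  }
  list(model = model, record = record, checkpoint = ckpt)
}
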