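#' Full-run configuration
#'
#' Bundles the synthetic-data, pseudo-label, training and
#' confident-learning settings of a complete two-stage run. Any element
#' can be overridden; the defaults give a desk-scale run (16 synthetic
#' 96 x 96 images, tiny networks) that exercises every stage on one CPU.
#'
#' @param data list: either `dir` (an existing dataset in the standard
#'   layout) or the generator settings `n_images`, `height`, `width`,
#'   `n_nuclei_range`, `seed`.
#' @param pseudo list of pseudo-label settings: `r_pt`, `ridge_width`,
#'   `n_segments`, `compactness`, `shift_r`, `color_norm_ref`.
#' @param train a [train_config()].
#' @param cl list: `scope` (`"per_image"` or `"pooled"`) and `rounds`
#'   (number of confident-learning passes; more than one is known to
#'   degrade the attention features, so the default is 1).
#' @param threshold binarisation threshold for evaluation.
#' @return a `run_config` list.
#' @export
run_config <- function(data = list(n_images = 16L, height = 96L, width = 96L,
                                   n_nuclei_range = c(2L, 6L), seed = 1L),
                       pseudo = list(),
                       train = train_config(epochs = 5L,
                                            net = net_config("tiny")),
                       cl = list(scope = "per_image", rounds = 1L),
                       threshold = 0.5) {
  structure(list(data = data, pseudo = pseudo, train = train, cl = cl,
                 threshold = threshold), class = "run_config")
}

## wrap a stage so failures are prefixed with the stage name
stage_try <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Predict probability maps and refine superpixel labels on disk
#'
#' Runs the trained stage-1 model over all dataset images, applies
#' confident-learning correction to the superpixel labels and writes
#' `<id>_refined.png`, `<id>_flips.png` and `cl_summary.json`.
#'
#' @param model trained `joint_model` or checkpoint path.
#' @param dataset_dir dataset in the standard layout.
#' @param pseudolabels_dir directory holding `<id>_superpixel.png`.
#' @param out_dir output directory.
#' @param scope confident-learning scope (see [refine_dataset()]).
#' @param rounds number of correction rounds (each round re-ranks using
#'   the same fixed probabilities against the current labels).
#' @return the final [refine_dataset()] result, invisibly.
#' @export
refine_labels <- function(model, dataset_dir, pseudolabels_dir, out_dir,
                          scope = "per_image", rounds = 1L) {
  model <- load_model_maybe(model)
  ids <- dataset_ids(dataset_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  probs <- list(); labels <- list()
  for (id in ids) {
    img <- read_image(file.path(dataset_dir, "images", paste0(id, ".png")))
    probs[[id]] <- predict_mask(model, img)
    labels[[id]] <- read_label(file.path(pseudolabels_dir,
                                         paste0(id, "_superpixel.png")))
  }
  res <- refine_maps(probs, labels, scope, rounds)
  for (id in ids) {
    write_label(res$refined[[id]], file.path(out_dir, paste0(id, "_refined.png")))
    write_label(res$flip_masks[[id]], file.path(out_dir, paste0(id, "_flips.png")))
  }
  summ <- res$summary
  summ$per_unit <- lapply(summ$per_unit, function(s)
    list(t = s$t, C = as.vector(s$C), Q = as.vector(s$Q),
         n_flips_0to1 = s$n_flips_0to1, n_flips_1to0 = s$n_flips_1to0))
  jsonlite::write_json(summ, file.path(out_dir, "cl_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

## Refinement over in-memory probability maps. Under per-image scope the
## images are independent: an image on which the model is confident about
## no pixel of one class (empty counting-matrix row) is left unrefined
## with a warning instead of failing the whole run.
refine_maps <- function(probs, labels, scope = "per_image", rounds = 1L) {
  ids <- names(probs)
  res <- NULL
  for (r in seq_len(max(1L, rounds))) {
    if (scope == "per_image") {
      parts <- lapply(ids, function(id) {
        tryCatch(refine_dataset(probs[id], labels[id], scope = "per_image"),
                 error = function(e) {
                   warning(sprintf("image '%s' left unrefined: %s", id,
                                   conditionMessage(e)), call. = FALSE)
                   list(refined = labels[id],
                        flip_masks = stats::setNames(
                          list(matrix(0L, nrow(labels[[id]]),
                                      ncol(labels[[id]]))), id),
                        summary = list(per_unit = stats::setNames(
                          list(NULL), id)))
                 })
      })
      res <- list(refined = do.call(c, lapply(parts, `[[`, "refined")),
                  flip_masks = do.call(c, lapply(parts, `[[`, "flip_masks")),
                  summary = list(scope = "per_image",
                                 per_unit = do.call(c, lapply(parts,
                                   function(p) p$summary$per_unit))))
      npx <- sum(vapply(res$flip_masks, length, 1L))
      res$summary$flip_fraction <-
        sum(unlist(lapply(res$flip_masks, sum))) / npx
      class(res) <- "cl_refinement"
    } else {
      res <- refine_dataset(probs, labels, scope = scope)
    }
    labels <- res$refined
  }
  res
}

#' Run the complete two-stage pipeline
#'
#' Generates (or loads) the data, builds pseudo-labels, trains stage 1,
#' refines the superpixel labels with confident learning, retrains
#' (stage 2) and evaluates both checkpoints against the ground-truth
#' masks. Every intermediate artifact is written under one run
#' directory, with the configuration copied in.
#'
#' @param config a [run_config()].
#' @param out_dir run directory (default: a timestamped directory under
#'   `tempdir()`).
#' @return an object of class `run_result`: list with `out_dir`,
#'   `metrics_stage1`, `metrics_stage2` (see [evaluate_model()]),
#'   `label_quality` (per-image pixel accuracy of the original and
#'   refined superpixel labels against ground truth, and the fraction of
#'   images the refinement improved or tied), `record1`, `record2` and
#'   the checkpoint paths.
#' @export
run_full <- function(config = run_config(),
                     out_dir = file.path(tempdir(),
                                         format(Sys.time(), "run-%Y%m%d-%H%M%S"))) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(serialize_run_config(config), cfg_file)

  data_dir <- stage_try("generate-data", {
    if (!is.null(config$data$dir)) config$data$dir
    else {
      dd <- file.path(out_dir, "data")
      generate_dataset(config$data$n_images, config$data$height,
                       config$data$width, config$data$n_nuclei_range,
                       config$data$seed %||% 1L, dir = dd)
      dd
    }
  })

  pl_dir <- file.path(out_dir, "pseudolabels")
  stage_try("pseudo-labels", do.call(make_pseudolabels, c(
    list(dataset_dir = data_dir, out_dir = pl_dir), config$pseudo)))

  s1 <- stage_try("train-stage1",
    train_stage1(data_dir, config$train, pseudolabels_dir = pl_dir,
                 run_dir = file.path(out_dir, "stage1")))

  cl_dir <- file.path(out_dir, "cl")
  stage_try("refine-labels",
    refine_labels(s1$model, data_dir, pl_dir, cl_dir,
                  scope = config$cl$scope %||% "per_image",
                  rounds = config$cl$rounds %||% 1L))

  s2 <- stage_try("train-stage2",
    train_stage2(data_dir, cl_dir, config$train, pseudolabels_dir = pl_dir,
                 run_dir = file.path(out_dir, "stage2")))

  images_dir <- file.path(data_dir, "images")
  masks_dir <- file.path(data_dir, "masks")
  m1 <- stage_try("evaluate",
    evaluate_model(s1$model, images_dir, masks_dir, config$threshold,
                   out_prefix = file.path(out_dir, "metrics_stage1")))
  m2 <- stage_try("evaluate",
    evaluate_model(s2$model, images_dir, masks_dir, config$threshold,
                   out_prefix = file.path(out_dir, "metrics_stage2")))

  lq <- stage_try("label-quality",
    label_quality_report(data_dir, pl_dir, cl_dir,
                         file.path(out_dir, "label_quality.json")))

  structure(list(out_dir = out_dir,
                 metrics_stage1 = m1, metrics_stage2 = m2,
                 label_quality = lq,
                 record1 = s1$record, record2 = s2$record,
                 checkpoint_stage1 = s1$checkpoint,
                 checkpoint_stage2 = s2$checkpoint),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  m1 <- attr(x$metrics_stage1, "mean"); m2 <- attr(x$metrics_stage2, "mean")
  cat("Two-stage weakly supervised run:", x$out_dir, "\n")
  cat(sprintf("  stage 1: mean IoU %.4f, mean Dice %.4f\n", m1[["iou"]], m1[["dice"]]))
  cat(sprintf("  stage 2: mean IoU %.4f, mean Dice %.4f\n", m2[["iou"]], m2[["dice"]]))
  cat(sprintf("  label refinement improved or tied %.0f%% of images (flip fraction %.4f)\n",
              100 * x$label_quality$improved_fraction,
              x$label_quality$flip_fraction))
  invisible(x)
}

## pixel accuracy of the original vs. refined superpixel labels against
## the synthetic ground truth
label_quality_report <- function(data_dir, pl_dir, cl_dir, out_file = NULL) {
  ids <- dataset_ids(data_dir)
  acc <- function(lab, gt) mean((lab != 0) == (gt != 0))
  rows <- lapply(ids, function(id) {
    gt <- read_mask(file.path(data_dir, "masks", paste0(id, ".png")))
    ys <- read_label(file.path(pl_dir, paste0(id, "_superpixel.png")))
    yre <- read_label(file.path(cl_dir, paste0(id, "_refined.png")))
    fl <- read_label(file.path(cl_dir, paste0(id, "_flips.png")))
    data.frame(id = id, acc_ys = acc(ys, gt), acc_yre = acc(yre, gt),
               flip_fraction = mean(fl != 0))
  })
  df <- do.call(rbind, rows)
  res <- list(per_image = df,
              improved_fraction = mean(df$acc_yre >= df$acc_ys),
              mean_acc_ys = mean(df$acc_ys),
              mean_acc_yre = mean(df$acc_yre),
              flip_fraction = mean(df$flip_fraction))
  if (!is.null(out_file))
    jsonlite::write_json(res, out_file, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  res
}

## flatten the run config into plain lists for the YAML copy
serialize_run_config <- function(config) {
  tr <- config$train
  list(data = config$data,
       pseudo = config$pseudo,
       train = list(lr = tr$lr, weight_decay = tr$weight_decay,
                    epochs = tr$epochs, batch_size = tr$batch_size,
                    plateau_patience_epochs = tr$plateau_patience_epochs,
                    lr_halving_factor = tr$lr_halving_factor,
                    loss_weights = unclass(tr$loss_weights),
                    net = unclass(tr$net)[c("preset", "width_multiplier",
                                            "use_deformable",
                                            "dilation_last_block",
                                            "consnet_n")],
                    augmentation = tr$augmentation,
                    seed = tr$seed, val_fraction = tr$val_fraction,
                    detach = tr$detach, att_neg_target = tr$att_neg_target),
       cl = config$cl, threshold = config$threshold)
}

#' Load a run configuration from a YAML file
#'
#' Reads the per-stage blocks written by [run_full()] (or hand-written in
#' the same layout) back into a [run_config()].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  tr <- y$train %||% list()
  train <- train_config(
    lr = tr$lr %||% 0.001, weight_decay = tr$weight_decay %||% 0.0005,
    epochs = tr$epochs %||% 60L, batch_size = tr$batch_size %||% 1L,
    plateau_patience_epochs = tr$plateau_patience_epochs %||% 4L,
    lr_halving_factor = tr$lr_halving_factor %||% 0.5,
    loss_weights = do.call(loss_weights, tr$loss_weights %||% list()),
    net = do.call(net_config, tr$net %||% list()),
    augmentation = tr$augmentation,
    seed = tr$seed %||% 1L, val_fraction = tr$val_fraction %||% 0.2,
    detach = tr$detach %||% TRUE, att_neg_target = tr$att_neg_target %||% 1)
  run_config(data = y$data %||% list(), pseudo = y$pseudo %||% list(),
             train = train, cl = y$cl %||% list(scope = "per_image", rounds = 1L),
             threshold = y$threshold %||% 0.5)
}
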