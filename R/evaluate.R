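#' Pixel-overlap metrics
#'
#' Intersection-over-union and Dice coefficient between two binary masks.
#' Both are 1 when prediction and ground truth coincide; when both masks
#' are empty the metrics are defined as 1 (nothing to segment, nothing
#' segmented). The two measures are algebraically linked by
#' `Dice = 2 * IoU / (1 + IoU)`.
#'
#' @param pred,truth binary `H x W` matrices (any non-zero is foreground).
#' @return a single numeric value.
#' @export
iou_score <- function(pred, truth) {
  p <- pred != 0; t <- truth != 0
  u <- sum(p | t)
  if (u == 0) return(1)
  sum(p & t) / u
}

#' @rdname iou_score
#' @export
dice_score <- function(pred, truth) {
  p <- pred != 0; t <- truth != 0
  s <- sum(p) + sum(t)
  if (s == 0) return(1)
  2 * sum(p & t) / s
}

#' Evaluate a trained model against ground-truth masks
#'
#' Runs the segmentation forward pass on every image, thresholds the
#' foreground probability map and scores pixel IoU and Dice against the
#' ground truth.
#'
#' @param model a trained model (see [train_stage1()]) or a checkpoint
#'   path saved by the training functions.
#' @param images_dir directory of input images (`<id>.png`).
#' @param gt_masks_dir directory of ground-truth masks (`<id>.png`, 0/255).
#' @param threshold binarisation threshold on the probability map.
#' @param out_prefix optional path prefix; when given, metrics are written
#'   to `<out_prefix>.json` and `<out_prefix>.csv`.
#' @return an object of class `seg_metrics`: data frame with one row per
#'   image (`id`, `iou`, `dice`) plus a `mean` attribute, printed as a
#'   table.
#' @export
evaluate_model <- function(model, images_dir, gt_masks_dir, threshold = 0.5,
                           out_prefix = NULL) {
  model <- load_model_maybe(model)
  ids <- sort(sub("\\.png$", "", list.files(images_dir, pattern = "\\.png$")))
  rows <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    img <- read_image(file.path(images_dir, paste0(id, ".png")))
    gt <- read_mask(file.path(gt_masks_dir, paste0(id, ".png")))
    if (!identical(dim(img)[1:2], dim(gt)))
      stop(sprintf("image '%s' (%d x %d) and mask (%d x %d) disagree on shape",
                   id, dim(img)[1], dim(img)[2], dim(gt)[1], dim(gt)[2]),
           call. = FALSE)
    prob <- predict_mask(model, img)
    pred <- (prob >= threshold) * 1L
    rows[[k]] <- data.frame(id = id, iou = iou_score(pred, gt),
                            dice = dice_score(pred, gt))
  }
  df <- do.call(rbind, rows)
  means <- c(iou = mean(df$iou), dice = mean(df$dice))
  attr(df, "mean") <- means
  class(df) <- c("seg_metrics", "data.frame")
  if (!is.null(out_prefix)) {
    js <- c(stats::setNames(
      lapply(seq_len(nrow(df)),
             function(i) list(iou = df$iou[i], dice = df$dice[i])), df$id),
      list(mean = list(iou = means[["iou"]], dice = means[["dice"]])))
    jsonlite::write_json(js, paste0(out_prefix, ".json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(as.data.frame(df), paste0(out_prefix, ".csv"),
                     row.names = FALSE)
  }
  df
}

#' @export
print.seg_metrics <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  m <- attr(x, "mean")
  cat(sprintf("mean IoU %.4f, mean Dice %.4f over %d image(s)\n",
              m[["iou"]], m[["dice"]], nrow(x)))
  invisible(x)
}
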