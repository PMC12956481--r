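#' Pixel datasets for confident learning
#'
#' A `pixel_dataset` collects, for `n` pixels, the model's predicted class
#' probabilities (`m = 2` classes: background 0, foreground 1; the
#' foreground probability is the segmentation network's output `f(I)` and
#' the background probability its complement) together with the given
#' (possibly noisy) superpixel labels.
#'
#' @param probs `n x 2` matrix of class probabilities; each row must sum
#'   to 1 (tolerance 1e-6). Column 1 is class 0, column 2 class 1.
#' @param labels length-`n` vector of given labels in `{0, 1}`.
#' @param pixel_index optional data frame mapping rows back to
#'   `(image, row, col)`.
#' @return an object of class `pixel_dataset`.
#' @export
pixel_dataset <- function(probs, labels, pixel_index = NULL) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 2L)
    stop("`probs` must have two columns (background, foreground)",
         call. = FALSE)
  if (nrow(probs) != length(labels))
    stop("`probs` and `labels` disagree on length", call. = FALSE)
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop("probability rows must sum to 1", call. = FALSE)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be 0 or 1", call. = FALSE)
  structure(list(probs = probs, labels = labels, pixel_index = pixel_index),
            class = "pixel_dataset")
}

#' Class confidence thresholds
#'
#' The threshold of class `j` is the mean predicted probability of class
#' `j` over the pixels whose *given* label is `j` — the standard
#' confident-learning self-confidence threshold. A pixel only counts as a
#' confident member of class `j` if its predicted probability of `j`
#' exceeds `t_j`.
#'
#' @param data a [pixel_dataset()].
#' @return numeric vector `t` of length 2 (classes 0 and 1).
#' @export
class_thresholds <- function(data) {
  stopifnot(inherits(data, "pixel_dataset"))
  t <- numeric(2)
  for (j in 0:1) {
    sel <- data$labels == j
    if (!any(sel))
      stop(sprintf("no pixels carry label %d: cannot form its threshold", j),
           call. = FALSE)
    t[j + 1] <- mean(data$probs[sel, j + 1])
  }
  t
}

#' Confident-learning counting matrix
#'
#' `C[i, j]` counts the pixels whose given label is `i`, whose predicted
#' class (argmax probability) is `j`, and whose predicted probability of
#' `j` strictly exceeds the class threshold `t_j`. Pixels failing the
#' threshold are left uncounted. The degenerate `t_j = 1` case (perfectly
#' confident predictions everywhere) relaxes the strict inequality to
#' `>=` so those pixels are not all discarded.
#'
#' @param data a [pixel_dataset()].
#' @param t class thresholds from [class_thresholds()].
#' @return 2 x 2 integer matrix with rows = given label (0, 1) and
#'   columns = predicted label (0, 1).
#' @export
counting_matrix <- function(data, t) {
  stopifnot(inherits(data, "pixel_dataset"), length(t) == 2L)
  pred <- max.col(data$probs, ties.method = "first") - 1L
  ppred <- data$probs[cbind(seq_along(pred), pred + 1L)]
  conf <- ifelse(t[pred + 1L] >= 1, ppred >= t[pred + 1L],
                 ppred > t[pred + 1L])
  C <- matrix(0L, 2, 2, dimnames = list(given = 0:1, predicted = 0:1))
  for (i in 0:1) for (j in 0:1)
    C[i + 1, j + 1] <- sum(data$labels == i & pred == j & conf)
  C
}

#' Joint distribution between given and latent true labels
#'
#' Each row `i` of the counting matrix is rescaled to sum to the number
#' of pixels actually labeled `i` (calibration to the label frequencies),
#' then the whole matrix is normalised to sum to 1. Off-diagonal mass
#' estimates the label-noise rates.
#'
#' @param C counting matrix from [counting_matrix()].
#' @param data the [pixel_dataset()] the matrix was computed from.
#' @return 2 x 2 numeric matrix `Q` summing to 1.
#' @export
joint_distribution <- function(C, data) {
  stopifnot(inherits(data, "pixel_dataset"))
  rs <- rowSums(C)
  if (any(rs == 0))
    stop(paste("counting matrix has an empty row: the model is confident",
               "about no pixel of that class; train longer or lower the",
               "thresholds"), call. = FALSE)
  nlab <- c(sum(data$labels == 0L), sum(data$labels == 1L))
  Qt <- C * (nlab / rs)     # row i rescaled to |X_{y_s = i}|
  Qt / sum(Qt)
}

#' Flip the most confidently mislabeled pixels
#'
#' For each off-diagonal cell `(i, j)` of `Q`, the pixels with given label
#' `i` are ranked by the margin `p(j) - p(i)` in decreasing order and the
#' top `round(n * Q[i, j])` are flipped to `j` (round half away from
#' zero). If fewer label-`i` pixels exist than requested, all available
#' ones are flipped with a warning.
#'
#' @param data a [pixel_dataset()].
#' @param Q joint distribution from [joint_distribution()].
#' @return list with `labels` (corrected label vector) and `flipped`
#'   (logical vector marking corrected pixels).
#' @export
correct_labels <- function(data, Q) {
  stopifnot(inherits(data, "pixel_dataset"))
  n <- length(data$labels)
  labels <- data$labels
  flipped <- logical(n)
  for (i in 0:1) {
    j <- 1L - i
    k <- as.integer(round_half_away(n * Q[i + 1, j + 1]))
    if (k <= 0L) next
    cand <- which(data$labels == i)
    if (k > length(cand)) {
      warning(sprintf(
        "requested %d flips from label %d but only %d pixels available",
        k, i, length(cand)))
      k <- length(cand)
    }
    if (k == 0L) next
    margin <- data$probs[cand, j + 1] - data$probs[cand, i + 1]
    ord <- cand[order(-margin, cand)]
    sel <- ord[seq_len(k)]
    labels[sel] <- j
    flipped[sel] <- TRUE
  }
  list(labels = labels, flipped = flipped)
}

#' Refine superpixel labels of a dataset with confident learning
#'
#' Runs the full correction chain — class thresholds, counting matrix,
#' joint distribution, margin-ranked flips — over per-image probability
#' maps and their binary superpixel labels. With `scope = "per_image"`
#' (the default) every step is computed within each image; with
#' `scope = "pooled"` a single model over all pixels of all images is
#' used.
#'
#' @param prob_maps named list of `H x W` foreground-probability matrices
#'   (values in `[0, 1]`), one per image, from a trained stage-1 model in
#'   eval mode.
#' @param sp_labels named list of binary `H x W` superpixel label
#'   matrices, matching names.
#' @param scope `"per_image"` or `"pooled"`.
#' @return an object of class `cl_refinement`: list with `refined` (named
#'   list of corrected binary label matrices), `flip_masks` (named list of
#'   0/1 matrices marking corrected pixels), and `summary` (per-scope
#'   thresholds `t`, counting matrix `C`, joint `Q`, flip counts per
#'   direction and overall flip fraction).
#' @export
refine_dataset <- function(prob_maps, sp_labels, scope = c("per_image", "pooled")) {
  scope <- match.arg(scope)
  ids <- names(prob_maps)
  stopifnot(!is.null(ids), identical(sort(ids), sort(names(sp_labels))))
  refined <- list(); flips <- list()
  summaries <- list()

  run_one <- function(probs_fg, labels) {
    ds <- pixel_dataset(cbind(1 - probs_fg, probs_fg), labels)
    t <- class_thresholds(ds)
    C <- counting_matrix(ds, t)
    Q <- joint_distribution(C, ds)
    cor <- correct_labels(ds, Q)
    list(t = t, C = C, Q = Q, cor = cor)
  }

  if (scope == "per_image") {
    for (id in ids) {
      p <- prob_maps[[id]]; y <- sp_labels[[id]]
      res <- run_one(as.vector(p), as.vector(y))
      refined[[id]] <- matrix(res$cor$labels, nrow(y), ncol(y))
      flips[[id]] <- matrix(as.integer(res$cor$flipped), nrow(y), ncol(y))
      summaries[[id]] <- list(t = res$t, C = res$C, Q = res$Q,
                              n_flips_0to1 = sum(res$cor$flipped &
                                                 res$cor$labels == 1L),
                              n_flips_1to0 = sum(res$cor$flipped &
                                                 res$cor$labels == 0L))
    }
  } else {
    sizes <- vapply(prob_maps, length, 1L)
    p_all <- unlist(lapply(ids, function(id) as.vector(prob_maps[[id]])))
    y_all <- unlist(lapply(ids, function(id) as.vector(sp_labels[[id]])))
    res <- run_one(p_all, y_all)
    off <- 0L
    for (id in ids) {
      y <- sp_labels[[id]]
      m <- length(y)
      lab <- res$cor$labels[off + seq_len(m)]
      fl <- res$cor$flipped[off + seq_len(m)]
      refined[[id]] <- matrix(lab, nrow(y), ncol(y))
      flips[[id]] <- matrix(as.integer(fl), nrow(y), ncol(y))
      off <- off + m
    }
    summaries$pooled <- list(t = res$t, C = res$C, Q = res$Q,
                             n_flips_0to1 = sum(res$cor$flipped &
                                                res$cor$labels == 1L),
                             n_flips_1to0 = sum(res$cor$flipped &
                                                res$cor$labels == 0L))
  }

  total_px <- sum(vapply(flips, length, 1L))
  structure(list(refined = refined, flip_masks = flips,
                 summary = list(scope = scope, per_unit = summaries,
                                flip_fraction =
                                  sum(unlist(lapply(flips, sum))) / total_px)),
            class = "cl_refinement")
}

#' @export
print.cl_refinement <- function(x, ...) {
  cat(sprintf("<cl_refinement: %d images, scope '%s', flip fraction %.4f>\n",
              length(x$refined), x$summary$scope, x$summary$flip_fraction))
  invisible(x)
}
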