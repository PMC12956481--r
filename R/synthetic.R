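#' Generate a synthetic histology-like scene with exact ground truth
#'
#' Renders textured elliptical nuclei (dark purple, per-nucleus colour
#' jitter) on a lighter pink textured background, mimicking an H&E tile.
#' Every nucleus comes with its exact instance mask and a centroid point,
#' so pseudo-label generation, training and label-correction can all be
#' tested without any external dataset.
#'
#' Nuclei are rotated ellipses with semi-axes drawn uniformly from
#' `axis_range` (in pixels at a 96 px reference frame, scaled linearly with
#' `min(height, width)`). Placement is rejection-sampled: when
#' `overlap_allowed` is `TRUE` (the default) a candidate is accepted if its
#' pairwise IoU with every existing nucleus is at most `max_overlap_iou`,
#' emulating the frequent partial overlap of nuclei in tissue; with
#' `overlap_allowed = FALSE` candidates must be disjoint. The centroid of a
#' clipped instance is recomputed from the rendered mask, never taken from
#' the analytic ellipse centre.
#'
#' @param height,width image size in pixels (each at least 32).
#' @param n_nuclei number of nuclei to place (may be 0).
#' @param seed integer seed; scenes are bit-identical for a fixed seed.
#' @param overlap_allowed allow partially overlapping nuclei (default TRUE).
#' @param axis_range semi-axis range in px at the 96 px reference scale.
#' @param max_overlap_iou pairwise IoU cap when overlap is allowed.
#' @param bg_mean,nucleus_mean RGB means on the 0-255 scale.
#' @param color_jitter_sd per-nucleus RGB jitter SD (0-255 scale).
#' @param noise_sd additive per-pixel Gaussian noise SD (0-255 scale).
#' @param max_attempts placement attempts per nucleus before giving up.
#' @return an object of class `synthetic_scene`: list with `image`
#'   (H x W x 3 array in \[0,1\], quantized to the 8-bit grid),
#'   `instance_masks` (list of H x W 0/1 matrices), `gt_mask` (their
#'   pixel-wise union), `points` (a [point_set], one centroid per
#'   instance) and `seed`.
#' @examples
#' sc <- generate_scene(64, 64, 5, seed = 7)
#' sum(sc$gt_mask) > 0
#' @export
generate_scene <- function(height, width, n_nuclei, seed,
                           overlap_allowed = TRUE,
                           axis_range = c(2, 6),
                           max_overlap_iou = 0.3,
                           bg_mean = c(230, 200, 220),
                           nucleus_mean = c(110, 70, 140),
                           color_jitter_sd = 15,
                           noise_sd = 8,
                           max_attempts = 80L) {
  if (height < 32 || width < 32)
    stop("height and width must be at least 32", call. = FALSE)
  if (n_nuclei < 0) stop("n_nuclei must be >= 0", call. = FALSE)
  with_seed(seed, {
    scale <- min(height, width) / 96
    ax <- axis_range * scale
    npx <- height * width
    rr <- matrix(rep(0:(height - 1), width), height, width)   # 0-based rows
    cc <- matrix(rep(0:(width - 1), each = height), height, width)

    masks <- list()
    centroids <- matrix(integer(0), ncol = 2)
    k <- 0L
    attempts_left <- max_attempts * max(n_nuclei, 1L)
    while (k < n_nuclei) {
      if (attempts_left <= 0L)
        stop(sprintf(
          "could not place %d nuclei in a %d x %d frame (placement failed after bounded attempts)",
          n_nuclei, height, width), call. = FALSE)
      attempts_left <- attempts_left - 1L
      cy <- stats::runif(1, 0, height - 1)
      cx <- stats::runif(1, 0, width - 1)
      a <- stats::runif(1, ax[1], ax[2])
      b <- stats::runif(1, ax[1], ax[2])
      phi <- stats::runif(1, 0, pi)
      dy <- rr - cy; dx <- cc - cx
      u <- dx * cos(phi) + dy * sin(phi)
      v <- -dx * sin(phi) + dy * cos(phi)
      mask <- matrix(as.integer((u / a)^2 + (v / b)^2 <= 1), height, width)
      area <- sum(mask)
      if (area < 4L) next  # clipped away or degenerate
      ok <- TRUE
      for (m in masks) {
        inter <- sum(mask & m)
        if (inter > 0L) {
          if (!overlap_allowed) { ok <- FALSE; break }
          iou <- inter / sum(mask | m)
          if (iou > max_overlap_iou) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      idx <- which(mask == 1L)
      ctr <- c(round(mean(rr[idx])), round(mean(cc[idx])))
      ## rounded centroid of a clipped ellipse can fall outside; snap to mask
      if (mask[ctr[1] + 1, ctr[2] + 1] != 1L) {
        d2 <- (rr[idx] - ctr[1])^2 + (cc[idx] - ctr[2])^2
        j <- idx[which.min(d2)]
        ctr <- c(rr[j], cc[j])
      }
      if (nrow(centroids) && any(centroids[, 1] == ctr[1] &
                                 centroids[, 2] == ctr[2])) next
      k <- k + 1L
      masks[[k]] <- mask
      centroids <- rbind(centroids, ctr)
    }

    img <- array(rep(bg_mean / 255, each = npx), c(height, width, 3))
    for (i in seq_len(k)) {
      col <- (nucleus_mean + stats::rnorm(3, 0, color_jitter_sd)) / 255
      sel <- masks[[i]] == 1L
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[sel] <- col[ch]
        img[, , ch] <- plane
      }
    }
    img <- img + array(stats::rnorm(npx * 3, 0, noise_sd / 255),
                       c(height, width, 3))
    img <- quantize8(img)

    gt <- matrix(0L, height, width)
    for (m in masks) gt <- pmax(gt, m)

    structure(list(image = img,
                   instance_masks = masks,
                   gt_mask = gt,
                   points = point_set(centroids, c(height, width)),
                   seed = as.integer(seed)),
              class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<synthetic_scene: %d x %d, %d nuclei, seed %d>\n",
              d[1], d[2], length(x$instance_masks), x$seed))
  invisible(x)
}

#' Generate a dataset of synthetic scenes
#'
#' Per-image seeds are derived deterministically from the master seed, so
#' the same call always yields the same scenes (and identical files when
#' written to disk).
#'
#' @param n_images number of scenes (at least 1).
#' @param height,width image size in pixels.
#' @param n_nuclei_range integer pair `c(lo, hi)`; per-image nucleus counts
#'   are drawn uniformly from this range.
#' @param seed master seed.
#' @param dir optional directory; when given the dataset is written in the
#'   on-disk layout `images/<id>.png`, `masks/<id>.png` (0/255),
#'   `points/<id>.csv` (0-based `row,col`) and `meta.json`.
#' @param ... further arguments passed to [generate_scene()].
#' @return invisibly, a named list of `synthetic_scene` objects (names are
#'   the image ids `img001`, `img002`, ...).
#' @export
generate_dataset <- function(n_images, height, width, n_nuclei_range, seed,
                             dir = NULL, ...) {
  if (n_images < 1) stop("n_images must be >= 1", call. = FALSE)
  n_nuclei_range <- as.integer(n_nuclei_range)
  seeds <- derive_seeds(seed, n_images + 1L)
  counts <- if (n_nuclei_range[1] == n_nuclei_range[2])
    rep(n_nuclei_range[1], n_images)
  else
    with_seed(seeds[n_images + 1L],
              sample(n_nuclei_range[1]:n_nuclei_range[2],
                     n_images, replace = TRUE))
  ids <- sprintf("img%03d", seq_len(n_images))
  scenes <- vector("list", n_images)
  names(scenes) <- ids
  for (i in seq_len(n_images))
    scenes[[i]] <- generate_scene(height, width, counts[i], seeds[i], ...)
  if (!is.null(dir)) write_scene_dataset(scenes, dir, seed)
  invisible(scenes)
}

#' Write a list of scenes in the standard dataset layout
#'
#' @param scenes named list of `synthetic_scene` objects.
#' @param dir output directory (created if missing).
#' @param seed master seed recorded in `meta.json`.
#' @return `dir`, invisibly.
#' @export
write_scene_dataset <- function(scenes, dir, seed = NA) {
  for (sub in c("images", "masks", "points"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  for (id in names(scenes)) {
    sc <- scenes[[id]]
    write_image(sc$image, file.path(dir, "images", paste0(id, ".png")))
    write_mask(sc$gt_mask, file.path(dir, "masks", paste0(id, ".png")))
    write_points(sc$points, file.path(dir, "points", paste0(id, ".csv")))
  }
  d <- dim(scenes[[1]]$image)
  meta <- list(seed = seed, n_images = length(scenes),
               height = d[1], width = d[2], ids = names(scenes))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

## List image ids present in a dataset directory.
dataset_ids <- function(dir) {
  ids <- sort(sub("\\.png$", "", list.files(file.path(dir, "images"),
                                            pattern = "\\.png$")))
  if (!length(ids))
    stop(sprintf("no images found under '%s/images'", dir), call. = FALSE)
  ids
}
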