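#' Build the binary superpixel pseudo-label
#'
#' Runs SLIC on the RGB image and labels as foreground exactly the union
#' of superpixels that contain at least one annotation point; all other
#' pixels are background. This is the boundary-adhering complement to the
#' Voronoi label: SLIC blocks hug local colour edges, so the pseudo-label
#' captures nucleus contours that the polygonal Voronoi partition misses.
#'
#' @param image `H x W x 3` RGB array in `[0, 1]`.
#' @param points a [point_set]; an empty set yields an all-background
#'   label with a warning.
#' @param n_segments number of SLIC superpixels; default `H*W / 150`.
#' @param compactness SLIC compactness (see [slic_superpixels()]).
#' @return an object of class `superpixel_label`: list with `label`
#'   (binary `H x W` matrix, no unlabeled code) and `sp_index` (the 0-based
#'   SLIC membership map).
#' @export
make_superpixel_label <- function(image, points,
                                  n_segments = NULL, compactness = 10) {
  assert_image(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  stopifnot(inherits(points, "point_set"))
  if (any(points$shape != c(H, W)))
    stop("image and points disagree on shape", call. = FALSE)
  n_segments <- n_segments %||% max(1L, round(H * W / 150))
  sp <- slic_superpixels(image, n_segments, compactness)
  lab <- matrix(LABEL_NEG, H, W)
  if (nrow(points$coords) == 0L) {
    warning("empty point set: superpixel label is all background")
  } else {
    fg_ids <- unique(sp[cbind(points$coords[, 1] + 1L,
                              points$coords[, 2] + 1L)])
    lab[matrix(sp %in% fg_ids, H, W)] <- LABEL_POS
  }
  structure(list(label = lab, sp_index = sp), class = "superpixel_label")
}

#' Perturb annotation points by a fixed radius
#'
#' Emulates noisy point annotations: each point is displaced by exactly
#' `r` pixels in an independent uniform random direction, rounded to the
#' pixel grid. The integer displacement is chosen among lattice points
#' whose Euclidean norm lies within 0.5 of `r` (plain coordinate rounding
#' can err in norm by up to `sqrt(2)/2`), picking the candidate closest to
#' the ideal real-valued displacement. Points are clipped to the frame;
#' if a displacement would collide with another point or leave the frame
#' degenerate, a fresh direction is drawn (bounded retries, then the point
#' is kept unperturbed). `r = 0` is the identity.
#'
#' @param points a [point_set].
#' @param r displacement radius in pixels (`>= 0`).
#' @param seed integer seed; output is deterministic per seed.
#' @return a [point_set] with displaced coordinates.
#' @export
perturb_points <- function(points, r, seed) {
  stopifnot(inherits(points, "point_set"))
  if (r < 0) stop("r must be >= 0", call. = FALSE)
  if (r == 0 || nrow(points$coords) == 0L) return(points)

  ## lattice annulus: integer displacements with | |d| - r | <= 0.5
  rng <- ceiling(r) + 1L
  g <- expand.grid(dy = -rng:rng, dx = -rng:rng)
  nrm <- sqrt(g$dy^2 + g$dx^2)
  cand <- g[abs(nrm - r) <= 0.5, , drop = FALSE]
  if (nrow(cand) == 0L)  # tiny radii between lattice shells
    cand <- g[abs(nrm - r) <= sqrt(2) / 2, , drop = FALSE]

  H <- points$shape[1]; W <- points$shape[2]
  with_seed(seed, {
    coords <- points$coords
    out <- coords
    for (i in seq_len(nrow(coords))) {
      for (try in 1:20) {
        th <- stats::runif(1, 0, 2 * pi)
        ideal <- c(r * sin(th), r * cos(th))
        d2 <- (cand$dy - ideal[1])^2 + (cand$dx - ideal[2])^2
        d <- c(cand$dy[which.min(d2)], cand$dx[which.min(d2)])
        p <- c(min(max(coords[i, 1] + d[1], 0L), H - 1L),
               min(max(coords[i, 2] + d[2], 0L), W - 1L))
        clash <- any(out[-i, 1] == p[1] & out[-i, 2] == p[2])
        if (!clash) { out[i, ] <- p; break }
      }
    }
    point_set(out, points$shape)
  })
}

#' Reinhard colour normalisation
#'
#' Matches the per-channel mean and standard deviation of the image to a
#' reference image in CIELab space, then converts back to sRGB and clips
#' to the valid range. This is the classic parameter-free stain
#' normalisation used to reduce colour variation across H&E slides.
#'
#' @param image,reference_image `H x W x 3` RGB arrays in `[0, 1]` (shapes
#'   may differ; only the reference's channel statistics are used).
#' @return the normalised image. A constant-valued image (zero standard
#'   deviation in some Lab channel) is returned unchanged with a warning.
#' @export
color_normalize <- function(image, reference_image) {
  assert_image(image); assert_image(reference_image, "reference_image")
  lab <- rgb_to_lab(image)
  ref <- rgb_to_lab(reference_image)
  out <- lab
  for (ch in 1:3) {
    s_img <- stats::sd(lab[, , ch])
    if (s_img < 1e-8) {
      warning("constant-valued image channel: returning image unchanged")
      return(image)
    }
    s_ref <- stats::sd(ref[, , ch])
    out[, , ch] <- (lab[, , ch] - mean(lab[, , ch])) * (s_ref / s_img) +
      mean(ref[, , ch])
  }
  lab_to_rgb(out)
}

#' Generate pseudo-labels for a dataset directory
#'
#' Reads `images/<id>.png` and `points/<id>.csv` from `dataset_dir` and
#' writes `<id>_voronoi.png` (coded tri-state), `<id>_superpixel.png`
#' (coded binary) and `<id>_spindex.csv` (SLIC membership) under `out_dir`.
#' Optional preprocessing: point perturbation by radius `shift_r` and
#' Reinhard normalisation against `color_norm_ref`.
#'
#' @param dataset_dir dataset in the standard layout (see
#'   [generate_dataset()]).
#' @param out_dir output directory.
#' @param r_pt,ridge_width Voronoi label parameters
#'   (see [make_voronoi_label()]).
#' @param n_segments,compactness SLIC parameters.
#' @param shift_r optional point-perturbation radius (0 = none).
#' @param seed seed for the perturbation.
#' @param color_norm_ref optional path of a reference image for colour
#'   normalisation.
#' @return invisibly, the vector of processed image ids.
#' @export
make_pseudolabels <- function(dataset_dir, out_dir,
                              r_pt = 2L, ridge_width = 1L,
                              n_segments = NULL, compactness = 10,
                              shift_r = 0, seed = 1L,
                              color_norm_ref = NULL) {
  ids <- dataset_ids(dataset_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ref <- if (!is.null(color_norm_ref)) read_image(color_norm_ref)
  seeds <- derive_seeds(seed, length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    img <- read_image(file.path(dataset_dir, "images", paste0(id, ".png")))
    if (!is.null(ref)) img <- color_normalize(img, ref)
    pts <- read_points(file.path(dataset_dir, "points", paste0(id, ".csv")),
                       dim(img)[1:2])
    if (shift_r > 0) pts <- perturb_points(pts, shift_r, seeds[i])
    vor <- make_voronoi_label(pts, r_pt = r_pt, ridge_width = ridge_width)
    spl <- make_superpixel_label(img, pts, n_segments, compactness)
    write_label(vor$label, file.path(out_dir, paste0(id, "_voronoi.png")))
    write_label(spl$label, file.path(out_dir, paste0(id, "_superpixel.png")))
    utils::write.csv(spl$sp_index,
                     file.path(out_dir, paste0(id, "_spindex.csv")),
                     row.names = FALSE)
  }
  invisible(ids)
}
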