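#' Voronoi partition of an image by annotation points
#'
#' Assigns every pixel to its nearest annotation point under Euclidean
#' distance (the nearest-centroid / distance-transform partition), ties
#' broken by the lowest point index. The number of cells equals the number
#' of points.
#'
#' @param points a [point_set] with at least one point.
#' @param shape image shape `c(H, W)`; defaults to the point set's shape.
#' @return integer `H x W` matrix of 0-based cell indices (`cell_index[p]`
#'   is the index of the nearest point, `0 ..  n_points - 1`).
#' @export
voronoi_partition <- function(points, shape = points$shape) {
  stopifnot(inherits(points, "point_set"))
  n <- nrow(points$coords)
  if (n == 0L) stop("voronoi_partition needs at least one point", call. = FALSE)
  H <- shape[1]; W <- shape[2]
  if (n == 1L) return(matrix(0L, H, W))
  rr <- rep(0:(H - 1), W)
  cc <- rep(0:(W - 1), each = H)
  ## squared distance matrix (H*W) x n, column-wise per point
  pr <- points$coords[, 1]; pc <- points$coords[, 2]
  D <- outer(rr, pr, function(a, b) (a - b)^2) +
       outer(cc, pc, function(a, b) (a - b)^2)
  idx <- max.col(-D, ties.method = "first") - 1L
  matrix(as.integer(idx), H, W)
}

## Pixels whose (2w+1)-square Chebyshev neighbourhood spans >= 2 Voronoi
## cells: the inter-cell ridges used as negative (background) labels.
voronoi_ridges <- function(cell_index, ridge_width = 1L) {
  H <- nrow(cell_index); W <- ncol(cell_index)
  ridge <- matrix(FALSE, H, W)
  w <- as.integer(ridge_width)
  for (dy in -w:w) {
    rs <- pmin(pmax(seq_len(H) + dy, 1L), H)
    for (dx in -w:w) {
      if (dy == 0L && dx == 0L) next
      cs <- pmin(pmax(seq_len(W) + dx, 1L), W)
      ridge <- ridge | (cell_index[rs, cs, drop = FALSE] != cell_index)
    }
  }
  ridge
}

#' Build the tri-state Voronoi pseudo-label from point annotations
#'
#' Positives are discs of radius `r_pt` around the annotation points
#' (dilated points); negatives are the pixels on Voronoi ridges — where a
#' `ridge_width`-radius neighbourhood spans at least two cells — minus the
#' positives; everything else is unlabeled (`255`). The positive and
#' negative sets are disjoint by construction and each Voronoi cell
#' contains exactly one point.
#'
#' @param points a [point_set] with at least one point.
#' @param shape image shape `c(H, W)`.
#' @param r_pt dilation radius of the point positives, in pixels
#'   (`r_pt = 0` keeps only the point pixels themselves).
#' @param ridge_width Chebyshev radius used to detect ridge pixels.
#' @return an object of class `voronoi_label`: list with `label` (coded
#'   `H x W` matrix, 1 positive / 0 negative / 255 unlabeled) and
#'   `cell_index` (the [voronoi_partition()] map).
#' @export
make_voronoi_label <- function(points, shape = points$shape,
                               r_pt = 2L, ridge_width = 1L) {
  if (r_pt < 0) stop("r_pt must be >= 0", call. = FALSE)
  cell <- voronoi_partition(points, shape)
  H <- shape[1]; W <- shape[2]
  rr <- rep(0:(H - 1), W)
  cc <- rep(0:(W - 1), each = H)
  pr <- points$coords[, 1]; pc <- points$coords[, 2]
  d2min <- matrix(Inf, H, W)
  for (i in seq_along(pr))
    d2min <- pmin(d2min, matrix((rr - pr[i])^2 + (cc - pc[i])^2, H, W))
  pos <- d2min <= r_pt^2
  neg <- if (nrow(points$coords) > 1L) voronoi_ridges(cell, ridge_width)
         else matrix(FALSE, H, W)
  lab <- matrix(LABEL_UNL, H, W)
  lab[neg] <- LABEL_NEG
  lab[pos] <- LABEL_POS  # positives take precedence over ridges
  structure(list(label = lab, cell_index = cell), class = "voronoi_label")
}
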