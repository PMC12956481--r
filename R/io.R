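#' Point sets: one annotation point per nucleus
#'
#' A `point_set` stores 0-based `(row, col)` pixel coordinates of nucleus
#' centroids together with the image shape they refer to. The 0-based
#' convention matches the on-disk CSV format (`row,col` header) and is used
#' by every public interface of the package.
#'
#' @param coords integer matrix with columns `row`, `col` (0-based), one row
#'   per point; a 0-row matrix or `NULL` gives an empty set.
#' @param shape integer vector `c(H, W)` of the image the points live on.
#' @return an object of class `point_set` with elements `coords` and `shape`.
#' @export
point_set <- function(coords, shape) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L))
    stop("`shape` must be c(H, W) with positive entries", call. = FALSE)
  if (is.null(coords) || NROW(coords) == 0L) {
    coords <- matrix(integer(0), ncol = 2L)
  } else {
    coords <- matrix(as.integer(round(coords)), ncol = 2L,
                     dimnames = NULL)
  }
  colnames(coords) <- c("row", "col")
  bad <- which(coords[, 1] < 0L | coords[, 1] >= shape[1] |
               coords[, 2] < 0L | coords[, 2] >= shape[2])
  if (length(bad))
    stop(sprintf("point %d (row=%d, col=%d) outside image of shape %d x %d",
                 bad[1], coords[bad[1], 1], coords[bad[1], 2],
                 shape[1], shape[2]), call. = FALSE)
  if (anyDuplicated(coords))
    stop("duplicate point coordinates are not allowed", call. = FALSE)
  structure(list(coords = coords, shape = shape), class = "point_set")
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set: %d points on %d x %d image>\n",
              nrow(x$coords), x$shape[1], x$shape[2]))
  invisible(x)
}

#' @export
length.point_set <- function(x) nrow(x$coords)

#' Read and write point annotations
#'
#' Points are stored as CSV files with header `row,col` holding 0-based
#' pixel coordinates. `read_points` validates every coordinate against
#' `shape` and reports the offending CSV row on failure.
#'
#' @param path CSV file path.
#' @param shape image shape `c(H, W)` the points must fall inside.
#' @return `read_points` returns a [point_set]; `write_points` returns
#'   `path` invisibly.
#' @export
read_points <- function(path, shape) {
  df <- utils::read.csv(path, colClasses = "integer")
  if (!all(c("row", "col") %in% names(df)))
    stop(sprintf("'%s' must have a 'row,col' header", path), call. = FALSE)
  shape <- as.integer(shape)
  bad <- which(df$row < 0L | df$row >= shape[1] |
               df$col < 0L | df$col >= shape[2])
  if (length(bad))
    stop(sprintf("'%s' row %d: point (%d, %d) outside image of shape %d x %d",
                 path, bad[1], df$row[bad[1]], df$col[bad[1]],
                 shape[1], shape[2]), call. = FALSE)
  point_set(cbind(df$row, df$col), shape)
}

#' @rdname read_points
#' @param points a [point_set].
#' @export
write_points <- function(points, path) {
  stopifnot(inherits(points, "point_set"))
  df <- as.data.frame(points$coords)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write RGB images
#'
#' Images are numeric arrays `H x W x 3` with values in `[0, 1]`. PNG and
#' TIFF are supported, chosen by file extension.
#'
#' @param path image file path (`.png`, `.tif` or `.tiff`).
#' @return `read_image` returns an `H x W x 3` array in `[0, 1]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '%s'", ext), call. = FALSE))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  img
}

#' @rdname read_image
#' @param image `H x W x 3` array in `[0, 1]`.
#' @export
write_image <- function(image, path) {
  assert_image(image)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(clip01(image), path),
    tif  = ,
    tiff = tiff::writeTIFF(clip01(image), path),
    stop(sprintf("unsupported image format '%s'", ext), call. = FALSE))
  invisible(path)
}

#' Read and write coded label maps
#'
#' Label maps are single-channel integer matrices with the coding
#' `0` = negative/background, `1` = positive/foreground and `255` =
#' unlabeled. They are stored as 8-bit grayscale PNGs carrying the raw
#' codes, so binary masks stay human-viewable (255 renders white).
#'
#' @param path PNG file path.
#' @return `read_label` returns an integer `H x W` matrix of codes.
#' @export
read_label <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  lab <- matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  if (!is_coded_label(lab))
    stop(sprintf("'%s' contains values other than the label codes 0/1/255",
                 path), call. = FALSE)
  lab
}

#' @rdname read_label
#' @param label integer `H x W` matrix with values in `{0, 1, 255}`.
#' @export
write_label <- function(label, path) {
  if (!is_coded_label(label))
    stop("`label` must be an H x W matrix with values in {0, 1, 255}",
         call. = FALSE)
  png::writePNG(label / 255, path)
  invisible(path)
}

#' Read and write binary masks
#'
#' Ground-truth masks use the plain 0/255 PNG convention (0 background,
#' 255 foreground) rather than the coded-label convention.
#'
#' @param path PNG file path.
#' @return `read_mask` returns an integer `H x W` matrix with values 0/1.
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(m > 0.5), nrow(m), ncol(m))
}

#' @rdname read_mask
#' @param mask integer `H x W` matrix (any non-zero value is foreground).
#' @export
write_mask <- function(mask, path) {
  png::writePNG((mask != 0) * 1, path)
  invisible(path)
}
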