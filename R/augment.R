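#' Joint augmentation of an image, its label maps and its points
#'
#' Applies geometric transforms (horizontal/vertical flips and a random
#' affine: rotation, isotropic scale, shear) identically to the image
#' (bilinear sampling), to every label map (nearest-neighbour sampling)
#' and to the point coordinates, followed by photometric transforms
#' (Gaussian blur, hue and saturation adjustment) on the image only.
#' All random draws are governed by `seed`, so the same call is
#' reproducible. Points transformed outside the frame are dropped and the
#' count is reported via a message.
#'
#' The `ops` configuration is a list; absent entries disable the
#' corresponding transform (an empty list is the identity):
#' \describe{
#'   \item{hflip, vflip}{flip probabilities in `[0, 1]`.}
#'   \item{affine}{list with `prob`, `rotation` (max degrees), `scale`
#'     (range pair), `shear` (max degrees).}
#'   \item{blur}{list with `prob` and `sigma` (range pair, pixels).}
#'   \item{hue}{maximum absolute hue shift (fraction of the hue circle).}
#'   \item{saturation}{maximum relative saturation change (e.g. 0.1
#'     scales saturation by a factor in `[0.9, 1.1]`).}
#' }
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param label_maps list of coded `H x W` matrices (may be empty). Pixels
#'   mapped from outside the frame are filled with 255 for tri-state maps
#'   and 0 for binary maps.
#' @param points a [point_set] or `NULL`.
#' @param ops configuration list, see Details.
#' @param seed integer seed.
#' @return list with `image`, `label_maps`, `points` and `n_dropped` (the
#'   number of points that left the frame).
#' @export
augment <- function(image, label_maps = list(), points = NULL,
                    ops = list(), seed = 1L) {
  assert_image(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  for (lm in label_maps)
    if (!identical(dim(lm), c(H, W)))
      stop("all label maps must share the image's H x W", call. = FALSE)
  if (!is.null(points) && any(points$shape != c(H, W)))
    stop("points and image disagree on shape", call. = FALSE)

  with_seed(seed, {
    do_h <- !is.null(ops$hflip) && stats::runif(1) < ops$hflip
    do_v <- !is.null(ops$vflip) && stats::runif(1) < ops$vflip
    aff <- NULL
    if (!is.null(ops$affine) &&
        stats::runif(1) < (ops$affine$prob %||% 1)) {
      rot <- (ops$affine$rotation %||% 30)
      sc <- ops$affine$scale %||% c(0.8, 1.2)
      sh <- ops$affine$shear %||% 10
      aff <- list(theta = stats::runif(1, -rot, rot) * pi / 180,
                  s = stats::runif(1, sc[1], sc[2]),
                  shear = stats::runif(1, -sh, sh) * pi / 180)
    }
    blur_sigma <- NULL
    if (!is.null(ops$blur) && stats::runif(1) < (ops$blur$prob %||% 1)) {
      sr <- ops$blur$sigma %||% c(0.5, 1.5)
      blur_sigma <- stats::runif(1, sr[1], sr[2])
    }
    dh <- if (!is.null(ops$hue)) stats::runif(1, -ops$hue, ops$hue) else 0
    fs <- if (!is.null(ops$saturation))
      stats::runif(1, 1 - ops$saturation, 1 + ops$saturation) else 1

    pts <- if (!is.null(points)) points$coords else NULL

    ## flips: exact index reflections
    if (do_h) {
      image <- image[, W:1, , drop = FALSE]
      label_maps <- lapply(label_maps, function(m) m[, W:1, drop = FALSE])
      if (!is.null(pts) && nrow(pts)) pts[, 2] <- W - 1L - pts[, 2]
    }
    if (do_v) {
      image <- image[H:1, , , drop = FALSE]
      label_maps <- lapply(label_maps, function(m) m[H:1, , drop = FALSE])
      if (!is.null(pts) && nrow(pts)) pts[, 1] <- H - 1L - pts[, 1]
    }

    n_dropped <- 0L
    if (!is.null(aff)) {
      M <- affine_matrix(aff$theta, aff$s, aff$shear)
      ctr <- c((H - 1) / 2, (W - 1) / 2)
      image <- warp_affine(image, M, ctr, interp = "bilinear")
      label_maps <- lapply(label_maps, function(m) {
        fill <- if (any(m == LABEL_UNL)) LABEL_UNL else LABEL_NEG
        warp_affine_label(m, M, ctr, fill)
      })
      if (!is.null(pts) && nrow(pts)) {
        q <- t(M %*% (t(pts) - ctr) + ctr)
        q <- round(q)
        keep <- q[, 1] >= 0 & q[, 1] <= H - 1 & q[, 2] >= 0 & q[, 2] <= W - 1
        n_dropped <- sum(!keep)
        if (n_dropped > 0L)
          message(sprintf("augment: dropped %d point(s) transformed outside the frame",
                          n_dropped))
        pts <- q[keep, , drop = FALSE]
        ## affine can merge rounded coordinates; keep unique points
        pts <- unique(pts)
      }
    }

    if (!is.null(blur_sigma)) image <- gaussian_blur(image, blur_sigma)
    if (dh != 0 || fs != 1) image <- adjust_hsv(image, dh, fs)

    list(image = quantize8(image),
         label_maps = label_maps,
         points = if (!is.null(points)) point_set(pts, c(H, W)) else NULL,
         n_dropped = n_dropped)
  })
}

## forward affine matrix acting on (row, col) offsets from the centre
affine_matrix <- function(theta, s, shear) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  Sh <- matrix(c(1, 0, tan(shear), 1), 2, 2)
  s * R %*% Sh
}

## inverse-warp an H x W x C image: output pixel p samples input at
## Minv (p - ctr) + ctr with bilinear interpolation and edge clamping
warp_affine <- function(image, M, ctr, interp = "bilinear") {
  H <- dim(image)[1]; W <- dim(image)[2]; C <- dim(image)[3]
  Minv <- solve(M)
  pr <- rep(0:(H - 1), W); pc <- rep(0:(W - 1), each = H)
  q <- Minv %*% rbind(pr - ctr[1], pc - ctr[2]) + ctr
  qr <- pmin(pmax(q[1, ], 0), H - 1)
  qc <- pmin(pmax(q[2, ], 0), W - 1)
  r0 <- floor(qr); c0 <- floor(qc)
  fr <- qr - r0; fc <- qc - c0
  r1 <- pmin(r0 + 1, H - 1); c1 <- pmin(c0 + 1, W - 1)
  i00 <- r0 + c0 * H + 1; i01 <- r0 + c1 * H + 1
  i10 <- r1 + c0 * H + 1; i11 <- r1 + c1 * H + 1
  out <- array(0, dim(image))
  for (ch in seq_len(C)) {
    v <- image[, , ch]
    out[, , ch] <- matrix(
      v[i00] * (1 - fr) * (1 - fc) + v[i01] * (1 - fr) * fc +
      v[i10] * fr * (1 - fc) + v[i11] * fr * fc, H, W)
  }
  out
}

## nearest-neighbour inverse warp of a coded label map with out-of-frame fill
warp_affine_label <- function(m, M, ctr, fill) {
  H <- nrow(m); W <- ncol(m)
  Minv <- solve(M)
  pr <- rep(0:(H - 1), W); pc <- rep(0:(W - 1), each = H)
  q <- Minv %*% rbind(pr - ctr[1], pc - ctr[2]) + ctr
  qr <- round(q[1, ]); qc <- round(q[2, ])
  inside <- qr >= 0 & qr <= H - 1 & qc >= 0 & qc <= W - 1
  idx <- pmin(pmax(qr, 0), H - 1) + pmin(pmax(qc, 0), W - 1) * H + 1
  vals <- m[idx]
  vals[!inside] <- fill
  matrix(as.integer(vals), H, W)
}

## separable Gaussian blur with edge replication
gaussian_blur <- function(image, sigma) {
  R <- max(1L, ceiling(3 * sigma))
  w <- exp(-(seq(-R, R))^2 / (2 * sigma^2)); w <- w / sum(w)
  H <- dim(image)[1]; W <- dim(image)[2]
  out <- image
  for (ch in 1:3) {
    v <- image[, , ch]
    tmp <- matrix(0, H, W)
    for (k in -R:R) {
      rs <- pmin(pmax(seq_len(H) + k, 1L), H)
      tmp <- tmp + v[rs, , drop = FALSE] * w[k + R + 1]
    }
    v2 <- matrix(0, H, W)
    for (k in -R:R) {
      cs <- pmin(pmax(seq_len(W) + k, 1L), W)
      v2 <- v2 + tmp[, cs, drop = FALSE] * w[k + R + 1]
    }
    out[, , ch] <- v2
  }
  out
}

## hue shift (fraction of the circle) and saturation scaling in HSV space
adjust_hsv <- function(image, dh, fs) {
  d <- dim(image)
  m <- matrix(c(image), d[1] * d[2], 3)
  hsv <- t(grDevices::rgb2hsv(t(m), maxColorValue = 1))
  h <- (hsv[, 1] + dh) %% 1
  s <- clip01(hsv[, 2] * fs)
  v <- hsv[, 3]
  ## numeric HSV -> RGB (vectorised)
  i <- floor(h * 6) %% 6
  f <- h * 6 - floor(h * 6)
  p <- v * (1 - s); q <- v * (1 - f * s); t_ <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t_, v)))))
  g <- ifelse(i == 0, t_, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t_,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  array(c(r, g, b), d)
}
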