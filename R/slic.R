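#' SLIC superpixel oversegmentation
#'
#' Simple linear iterative clustering: k-means in the joint CIELab + (x, y)
#' space, with cluster centres initialised on a regular grid (perturbed to
#' the lowest local colour-gradient position in a 3 x 3 window) and each
#' assignment pass restricted to a 2S x 2S window around a centre, where
#' `S = sqrt(H*W / n_segments)` is the grid interval. The distance between
#' a pixel and a centre is
#' `sqrt(d_lab^2 + (d_xy / S)^2 * compactness^2)`. A connectivity pass then
#' relabels stray components to an adjacent superpixel so every superpixel
#' is 4-connected.
#'
#' @param image `H x W x 3` RGB array in `[0, 1]`.
#' @param n_segments target number of superpixels.
#' @param compactness trade-off between colour proximity and spatial
#'   proximity; larger values give squarer superpixels.
#' @param n_iter number of assignment/update iterations.
#' @return integer `H x W` matrix of 0-based superpixel indices.
#' @export
slic_superpixels <- function(image, n_segments, compactness = 10,
                             n_iter = 10L) {
  assert_image(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  n_segments <- max(1L, as.integer(n_segments))
  lab <- rgb_to_lab(image)                 # H x W x 3
  S <- sqrt(H * W / n_segments)

  ## grid initialisation
  ny <- max(1L, round(H / S)); nx <- max(1L, round(W / S))
  cy0 <- (seq_len(ny) - 0.5) * H / ny
  cx0 <- (seq_len(nx) - 0.5) * W / nx
  centers <- expand.grid(y = cy0, x = cx0)
  ## perturb to the lowest gradient position in a 3x3 window
  L <- lab[, , 1]
  gy <- rbind(L[-1, , drop = FALSE], L[H, , drop = FALSE]) -
        rbind(L[1, , drop = FALSE], L[-H, , drop = FALSE])
  gx <- cbind(L[, -1, drop = FALSE], L[, W, drop = FALSE]) -
        cbind(L[, 1, drop = FALSE], L[, -W, drop = FALSE])
  grad <- gy^2 + gx^2
  K <- nrow(centers)
  cy <- numeric(K); cx <- numeric(K)
  for (k in seq_len(K)) {
    r0 <- min(max(round(centers$y[k] + 0.5), 2L), H - 1L)
    c0 <- min(max(round(centers$x[k] + 0.5), 2L), W - 1L)
    win <- grad[(r0 - 1):(r0 + 1), (c0 - 1):(c0 + 1)]
    j <- which.min(win)
    cy[k] <- r0 + ((j - 1) %% 3) - 1 - 1     # back to 0-based row
    cx[k] <- c0 + ((j - 1) %/% 3) - 1 - 1
  }
  cl <- matrix(0, K, 3)
  for (k in seq_len(K)) cl[k, ] <- lab[cy[k] + 1, cx[k] + 1, ]

  labmat <- matrix(c(lab), H * W, 3)
  rowg <- rep(0:(H - 1), W)
  colg <- rep(0:(W - 1), each = H)
  assign_idx <- rep(1L, H * W)
  best_d <- rep(Inf, H * W)
  m2s2 <- (compactness / S)^2

  for (it in seq_len(n_iter)) {
    best_d[] <- Inf
    for (k in seq_len(K)) {
      r1 <- max(0, floor(cy[k] - 2 * S)); r2 <- min(H - 1, ceiling(cy[k] + 2 * S))
      c1 <- max(0, floor(cx[k] - 2 * S)); c2 <- min(W - 1, ceiling(cx[k] + 2 * S))
      rs <- (r1:r2) + 1L; cs <- (c1:c2) + 1L
      pix <- as.vector(outer(rs, (cs - 1L) * H, "+"))
      d <- (labmat[pix, 1] - cl[k, 1])^2 +
           (labmat[pix, 2] - cl[k, 2])^2 +
           (labmat[pix, 3] - cl[k, 3])^2 +
           ((rowg[pix] - cy[k])^2 + (colg[pix] - cx[k])^2) * m2s2
      upd <- d < best_d[pix]
      if (any(upd)) {
        pu <- pix[upd]
        best_d[pu] <- d[upd]
        assign_idx[pu] <- k
      }
    }
    ## update centres
    for (k in seq_len(K)) {
      sel <- assign_idx == k
      if (!any(sel)) next
      cy[k] <- mean(rowg[sel]); cx[k] <- mean(colg[sel])
      cl[k, ] <- colMeans(labmat[sel, , drop = FALSE])
    }
  }

  enforce_connectivity(matrix(assign_idx - 1L, H, W),
                       min_size = floor(S * S / 4))
}

## Relabel connected components: components smaller than min_size (or
## secondary fragments of a superpixel) are merged into the previously
## visited neighbouring component; components are discovered in raster
## order with a BFS flood fill (4-connectivity).
enforce_connectivity <- function(seg, min_size) {
  H <- nrow(seg); W <- ncol(seg)
  n <- H * W
  out <- rep(-1L, n)
  segv <- as.integer(seg)
  comp <- 0L
  sizes <- integer(0)
  adjacent <- integer(0)   # a neighbouring (already labelled) component
  queue <- integer(n)
  members <- integer(n)
  for (p in seq_len(n)) {
    if (out[p] >= 0L) next
    lab <- segv[p]
    head <- 1L; tail <- 1L; queue[1] <- p
    out[p] <- comp
    cnt <- 0L
    adj <- -1L
    while (head <= tail) {
      q <- queue[head]; head <- head + 1L
      cnt <- cnt + 1L
      members[cnt] <- q
      r <- (q - 1L) %% H; c <- (q - 1L) %/% H
      for (d in 1:4) {
        nb <- switch(d,
          if (r > 0L) q - 1L else 0L,
          if (r < H - 1L) q + 1L else 0L,
          if (c > 0L) q - H else 0L,
          if (c < W - 1L) q + H else 0L)
        if (nb == 0L) next
        if (out[nb] < 0L && segv[nb] == lab) {
          out[nb] <- comp
          tail <- tail + 1L; queue[tail] <- nb
        } else if (out[nb] >= 0L && out[nb] != comp) {
          adj <- out[nb]
        }
      }
    }
    if (cnt < min_size && adj >= 0L) {
      out[members[seq_len(cnt)]] <- adj
      ## comp id not consumed
    } else {
      comp <- comp + 1L
      sizes <- c(sizes, cnt)
      adjacent <- c(adjacent, adj)
    }
  }
  ## compact ids (merging above may leave gaps)
  ids <- sort(unique(out))
  remap <- integer(max(ids) + 1L)
  remap[ids + 1L] <- seq_along(ids) - 1L
  matrix(remap[out + 1L], H, W)
}

## sRGB [0,1] -> CIELab via grDevices, returned as H x W x 3 array.
rgb_to_lab <- function(image) {
  d <- dim(image)
  m <- matrix(c(image), d[1] * d[2], 3)
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  array(c(lab), d)
}

## CIELab -> sRGB [0,1], clipped into gamut.
lab_to_rgb <- function(lab) {
  d <- dim(lab)
  m <- matrix(c(lab), d[1] * d[2], 3)
  rgb <- grDevices::convertColor(m, from = "Lab", to = "sRGB")
  array(clip01(c(rgb)), d)
}
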