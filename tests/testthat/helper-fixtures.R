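# shared fixtures and oracles for the suite

`%||%` <- function(a, b) if (is.null(a)) b else a

# central-difference numerical gradient of scalar-valued f at x
num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# brute-force nearest-point scan: the independent oracle for the Voronoi
# partition (per-pixel loop over points, lowest index wins ties)
voronoi_brute <- function(points, shape) {
  H <- shape[1]; W <- shape[2]
  out <- matrix(NA_integer_, H, W)
  for (r in 0:(H - 1)) for (cc in 0:(W - 1)) {
    d2 <- (points$coords[, 1] - r)^2 + (points$coords[, 2] - cc)^2
    out[r + 1, cc + 1] <- which.min(d2) - 1L   # which.min takes first min
  }
  out
}

# naive per-pixel loop oracle for the confident-learning counting matrix
counting_brute <- function(probs, labels, t) {
  C <- matrix(0L, 2, 2)
  for (z in seq_along(labels)) {
    j <- which.max(probs[z, ]) - 1L
    thr <- t[j + 1]
    ok <- if (thr >= 1) probs[z, j + 1] >= thr else probs[z, j + 1] > thr
    if (ok) C[labels[z] + 1, j + 1] <- C[labels[z] + 1, j + 1] + 1L
  }
  C
}

# one small cached scene reused by several test files
tiny_scene <- local({
  sc <- NULL
  function() {
    if (is.null(sc)) sc <<- generate_scene(64, 64, 5, seed = 7)
    sc
  }
})
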