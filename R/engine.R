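## Reverse-mode automatic differentiation engine for the network module.
##
## Values flow as plain numeric arrays (feature maps H x W x C, vectors for
## fully connected paths, length-1 scalars for losses). A forward pass runs
## inside a context holding a tape; every differentiable op appends a node
## (an environment with value, parents and a backward closure). backward()
## walks the tape in reverse, accumulating gradients into parameter
## environments. Inputs that are not nodes are treated as constants, so the
## same op functions double as plain numeric evaluators.
##
## This is deliberately a small, dependency-free engine: the networks here
## are compact encoder-decoders run one image at a time on CPU, and every
## layer's gradient is unit-tested against finite differences.

is_node <- function(x) inherits(x, "ps_node")

val <- function(x) if (is_node(x)) x$v else x

ctx_new <- function(training = FALSE) {
  ctx <- new.env(parent = emptyenv())
  ctx$nodes <- vector("list", 512L)
  ctx$n <- 0L
  ctx$training <- training
  ctx
}

node_new <- function(ctx, v, parents = list(), bw = NULL, param = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$v <- v; nd$g <- NULL; nd$parents <- parents; nd$bw <- bw
  nd$param <- param
  class(nd) <- "ps_node"
  ctx$n <- ctx$n + 1L
  if (ctx$n > length(ctx$nodes))
    ctx$nodes <- c(ctx$nodes, vector("list", length(ctx$nodes)))
  ctx$nodes[[ctx$n]] <- nd
  nd
}

## record an op; if no input is a node the plain value is returned, so op
## functions evaluate numerically outside any tape
op_record <- function(ctx, inputs, v, bw) {
  if (!any(vapply(inputs, is_node, TRUE))) return(v)
  node_new(ctx, v, parents = inputs, bw = bw)
}

nd_detach <- function(x) val(x)

backward <- function(ctx, loss) {
  stopifnot(is_node(loss))
  loss$g <- if (length(loss$v) == 1L) 1 else array(1, dim(loss$v))
  for (i in ctx$n:1) {
    nd <- ctx$nodes[[i]]
    if (is.null(nd$g)) next
    if (!is.null(nd$bw)) {
      grads <- nd$bw(nd$g)
      ps <- nd$parents
      for (k in seq_along(ps)) {
        p <- ps[[k]]
        if (is_node(p) && !is.null(grads[[k]]))
          p$g <- if (is.null(p$g)) grads[[k]] else p$g + grads[[k]]
      }
    }
    if (!is.null(nd$param)) nd$param$g <- nd$param$g + nd$g
  }
  invisible(NULL)
}

## ---- parameters -----------------------------------------------------------

ps_param <- function(v) {
  p <- new.env(parent = emptyenv())
  p$v <- v
  p$g <- array(0, dim(v) %||% length(v))
  p$m <- p$g; p$u <- p$g   # Adam state
  class(p) <- "ps_param"
  p
}

nd_param <- function(ctx, p) node_new(ctx, p$v, param = p)

zero_grads <- function(params) {
  for (p in params) p$g[] <- 0
  invisible(NULL)
}

## classic Adam with L2 weight decay added to the gradient
adam_step <- function(params, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  for (p in params) {
    g <- p$g + weight_decay * p$v
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$u <- beta2 * p$u + (1 - beta2) * g * g
    mhat <- p$m / (1 - beta1^t)
    uhat <- p$u / (1 - beta2^t)
    p$v <- p$v - lr * mhat / (sqrt(uhat) + eps)
    p$g[] <- 0
  }
  invisible(NULL)
}

collect_params <- function(x) {
  if (inherits(x, "ps_param")) return(list(x))
  if (is.list(x)) return(do.call(c, lapply(unname(x), collect_params)))
  list()
}

## ---- elementwise ops ------------------------------------------------------

## reduce a gradient to a scalar if the forward input was length-1
shrink <- function(g, ref) if (length(ref) == 1L && length(g) > 1L) sum(g) else g

nd_add <- function(ctx, a, b) {
  av <- val(a); bv <- val(b)
  op_record(ctx, list(a, b), av + bv,
            function(g) list(shrink(g, av), shrink(g, bv)))
}

nd_mul <- function(ctx, a, b) {
  av <- val(a); bv <- val(b)
  op_record(ctx, list(a, b), av * bv,
            function(g) list(shrink(g * bv, av), shrink(g * av, bv)))
}

nd_sub <- function(ctx, a, b) nd_add(ctx, a, nd_mul(ctx, b, -1))

nd_abs <- function(ctx, x) {
  xv <- val(x)
  op_record(ctx, list(x), abs(xv), function(g) list(g * sign(xv)))
}

nd_log <- function(ctx, x) {
  xv <- val(x)
  op_record(ctx, list(x), log(xv), function(g) list(g / xv))
}

nd_relu <- function(ctx, x) {
  xv <- val(x)
  op_record(ctx, list(x), pmax(xv, 0), function(g) list(g * (xv > 0)))
}

nd_sigmoid <- function(ctx, x) {
  s <- 1 / (1 + exp(-val(x)))
  op_record(ctx, list(x), s, function(g) list(g * s * (1 - s)))
}

## clamp with straight-through zero gradient outside (lo, hi)
nd_clamp <- function(ctx, x, lo, hi) {
  xv <- val(x)
  v <- pmin(pmax(xv, lo), hi)
  op_record(ctx, list(x), v, function(g) list(g * (xv > lo & xv < hi)))
}

nd_sum <- function(ctx, x) {
  xv <- val(x)
  op_record(ctx, list(x), sum(xv),
            function(g) list(array(g, dim(xv) %||% length(xv))))
}

nd_mean <- function(ctx, x) {
  xv <- val(x); n <- length(xv)
  op_record(ctx, list(x), mean(xv),
            function(g) list(array(g / n, dim(xv) %||% length(xv))))
}

## ---- structural ops -------------------------------------------------------

nd_concat_c <- function(ctx, a, b) {
  av <- val(a); bv <- val(b)
  ca <- dim(av)[3]
  v <- array(c(av, bv), c(dim(av)[1], dim(av)[2], ca + dim(bv)[3]))
  op_record(ctx, list(a, b), v, function(g) {
    list(g[, , seq_len(ca), drop = FALSE],
         g[, , -seq_len(ca), drop = FALSE])
  })
}

## per-channel scaling by a length-C vector (channel attention)
nd_scale_channels <- function(ctx, x, s) {
  xv <- val(x); sv <- val(s)
  d <- dim(xv); N <- d[1] * d[2]
  sb <- array(rep(sv, each = N), d)
  op_record(ctx, list(x, s), xv * sb, function(g) {
    list(g * sb, colSums(matrix(g * xv, N, d[3])))
  })
}

## per-pixel scaling by an H x W map across all channels (spatial attention)
nd_scale_spatial <- function(ctx, x, s) {
  xv <- val(x); sv <- val(s)
  d <- dim(xv); N <- d[1] * d[2]
  sm <- if (length(dim(sv)) == 3L) sv[, , 1] else sv
  sb <- array(rep(c(sm), d[3]), d)
  op_record(ctx, list(x, s), xv * sb, function(g) {
    ds <- matrix(rowSums(matrix(g * xv, N, d[3])), d[1], d[2])
    if (length(dim(sv)) == 3L) ds <- array(ds, dim(sv))
    list(g * sb, ds)
  })
}

## spatial global pooling: H x W x C -> length-C vector
nd_spatial_mean <- function(ctx, x) {
  xv <- val(x); d <- dim(xv); N <- d[1] * d[2]
  xm <- matrix(xv, N, d[3])
  op_record(ctx, list(x), colMeans(xm), function(g) {
    list(array(rep(g / N, each = N), d))
  })
}

nd_spatial_max <- function(ctx, x) {
  xv <- val(x); d <- dim(xv); N <- d[1] * d[2]
  xm <- matrix(xv, N, d[3])
  idx <- max.col(t(xm), ties.method = "first")
  op_record(ctx, list(x), xm[cbind(idx, seq_len(d[3]))], function(g) {
    dx <- matrix(0, N, d[3])
    dx[cbind(idx, seq_len(d[3]))] <- g
    list(array(dx, d))
  })
}

## channel pooling: H x W x C -> H x W x 1
nd_channel_mean <- function(ctx, x) {
  xv <- val(x); d <- dim(xv); N <- d[1] * d[2]
  xm <- matrix(xv, N, d[3])
  op_record(ctx, list(x), array(rowMeans(xm), c(d[1], d[2], 1L)),
            function(g) {
    list(array(rep(c(g) / d[3], d[3]), d))
  })
}

nd_channel_max <- function(ctx, x) {
  xv <- val(x); d <- dim(xv); N <- d[1] * d[2]
  xm <- matrix(xv, N, d[3])
  idx <- max.col(xm, ties.method = "first")
  op_record(ctx, list(x), array(xm[cbind(seq_len(N), idx)], c(d[1], d[2], 1L)),
            function(g) {
    dx <- matrix(0, N, d[3])
    dx[cbind(seq_len(N), idx)] <- c(g)
    list(array(dx, d))
  })
}

## fully connected on a vector: v = x %*% w + b
nd_dense <- function(ctx, x, w, b) {
  xv <- val(x); wv <- val(w); bv <- val(b)
  v <- drop(xv %*% wv) + bv
  op_record(ctx, list(x, w, b), v, function(g) {
    list(drop(wv %*% g), outer(xv, g), g)
  })
}

## 2x2 average pooling, stride 2 (even H, W)
nd_avgpool2 <- function(ctx, x) {
  xv <- val(x); d <- dim(xv)
  o <- seq(1, d[1], 2); e <- seq(2, d[1], 2)
  oc <- seq(1, d[2], 2); ec <- seq(2, d[2], 2)
  v <- (xv[o, oc, , drop = FALSE] + xv[o, ec, , drop = FALSE] +
        xv[e, oc, , drop = FALSE] + xv[e, ec, , drop = FALSE]) / 4
  op_record(ctx, list(x), v, function(g) {
    dx <- array(0, d)
    g4 <- g / 4
    dx[o, oc, ] <- g4; dx[o, ec, ] <- dx[o, ec, ] + g4
    dx[e, oc, ] <- dx[e, oc, ] + g4; dx[e, ec, ] <- dx[e, ec, ] + g4
    list(dx)
  })
}

## bilinear resize (half-pixel centres); separable weight matrices
resize_weights <- function(n_in, n_out) {
  src <- pmin(pmax(((seq_len(n_out) - 0.5) * n_in / n_out) - 0.5, 0), n_in - 1)
  i0 <- floor(src); w <- src - i0
  i1 <- pmin(i0 + 1, n_in - 1)
  Rw <- matrix(0, n_out, n_in)
  Rw[cbind(seq_len(n_out), i0 + 1)] <- Rw[cbind(seq_len(n_out), i0 + 1)] + 1 - w
  Rw[cbind(seq_len(n_out), i1 + 1)] <- Rw[cbind(seq_len(n_out), i1 + 1)] + w
  Rw
}

nd_resize <- function(ctx, x, h_out, w_out) {
  xv <- val(x); d <- dim(xv)
  if (d[1] == h_out && d[2] == w_out) return(x)
  Rw <- resize_weights(d[1], h_out)
  Cw <- resize_weights(d[2], w_out)
  v <- array(0, c(h_out, w_out, d[3]))
  for (ch in seq_len(d[3])) v[, , ch] <- Rw %*% xv[, , ch] %*% t(Cw)
  op_record(ctx, list(x), v, function(g) {
    dx <- array(0, d)
    for (ch in seq_len(d[3])) dx[, , ch] <- t(Rw) %*% g[, , ch] %*% Cw
    list(dx)
  })
}

## ---- convolution ----------------------------------------------------------

pad_hw <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  out[(p + 1):(p + d[1]), (p + 1):(p + d[2]), ] <- x
  out
}

conv_out_len <- function(n, k, stride, dilation, pad) {
  eff <- (k - 1L) * dilation + 1L
  (n + 2L * pad - eff) %/% stride + 1L
}

## 2D convolution, "same"-style padding dilation*(k-1)/2 (odd kernels)
nd_conv2d <- function(ctx, x, w, b, stride = 1L, dilation = 1L) {
  xv <- val(x); wv <- val(w); bv <- val(b)
  dw <- dim(wv); kh <- dw[1]; kw <- dw[2]; cin <- dw[3]; cout <- dw[4]
  pad <- dilation * (kh - 1L) %/% 2L
  xp <- pad_hw(xv, pad)
  H <- dim(xv)[1]; W <- dim(xv)[2]
  Ho <- conv_out_len(H, kh, stride, dilation, pad)
  Wo <- conv_out_len(W, kw, stride, dilation, pad)
  n_out <- Ho * Wo
  O <- matrix(rep(bv, each = n_out), n_out, cout)
  rows_l <- vector("list", kh); cols_l <- vector("list", kw)
  for (i in seq_len(kh))
    rows_l[[i]] <- seq.int((i - 1L) * dilation + 1L, by = stride,
                           length.out = Ho)
  for (j in seq_len(kw))
    cols_l[[j]] <- seq.int((j - 1L) * dilation + 1L, by = stride,
                           length.out = Wo)
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    Xm <- matrix(xp[rows_l[[i]], cols_l[[j]], , drop = FALSE], n_out, cin)
    O <- O + Xm %*% matrix(wv[i, j, , ], cin, cout)
  }
  v <- array(O, c(Ho, Wo, cout))
  op_record(ctx, list(x, w, b), v, function(g) {
    gm <- matrix(g, n_out, cout)
    db <- colSums(gm)
    dW <- array(0, dw)
    dxp <- array(0, dim(xp))
    for (i in seq_len(kh)) for (j in seq_len(kw)) {
      Xm <- matrix(xp[rows_l[[i]], cols_l[[j]], , drop = FALSE], n_out, cin)
      dW[i, j, , ] <- crossprod(Xm, gm)
      dXm <- gm %*% t(matrix(wv[i, j, , ], cin, cout))
      dxp[rows_l[[i]], cols_l[[j]], ] <-
        dxp[rows_l[[i]], cols_l[[j]], , drop = FALSE] +
        array(dXm, c(Ho, Wo, cin))
    }
    dx <- if (pad > 0L)
      dxp[(pad + 1):(pad + H), (pad + 1):(pad + W), , drop = FALSE]
    else dxp
    list(dx, dW, db)
  })
}

## Deformable convolution: each kernel tap samples the input at its regular
## grid position plus a learned fractional (dy, dx) offset, via bilinear
## interpolation. `offsets` has 2*kh*kw channels at the output resolution,
## ordered (dy, dx) per tap in row-major tap order. With all offsets zero
## the bilinear samples land exactly on the integer grid and the op equals
## nd_conv2d on the same kernel weights.
nd_dconv2d <- function(ctx, x, w, b, offsets, stride = 1L, dilation = 1L) {
  xv <- val(x); wv <- val(w); bv <- val(b); ov <- val(offsets)
  dw <- dim(wv); kh <- dw[1]; kw <- dw[2]; cin <- dw[3]; cout <- dw[4]
  pad <- dilation * (kh - 1L) %/% 2L
  xp <- pad_hw(xv, pad)
  Hp <- dim(xp)[1]; Wp <- dim(xp)[2]
  H <- dim(xv)[1]; W <- dim(xv)[2]
  Ho <- conv_out_len(H, kh, stride, dilation, pad)
  Wo <- conv_out_len(W, kw, stride, dilation, pad)
  n_out <- Ho * Wo
  stopifnot(dim(ov)[1] == Ho, dim(ov)[2] == Wo, dim(ov)[3] == 2L * kh * kw)
  Xpm <- matrix(xp, Hp * Wp, cin)
  O <- matrix(rep(bv, each = n_out), n_out, cout)
  cache <- vector("list", kh * kw)
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    tap <- (i - 1L) * kw + j
    rbase <- rep((0:(Ho - 1)) * stride + (i - 1L) * dilation + 1L, Wo)
    cbase <- rep((0:(Wo - 1)) * stride + (j - 1L) * dilation + 1L, each = Ho)
    sr_raw <- rbase + c(ov[, , 2L * tap - 1L])
    sc_raw <- cbase + c(ov[, , 2L * tap])
    sr <- pmin(pmax(sr_raw, 1), Hp)
    sc <- pmin(pmax(sc_raw, 1), Wp)
    r0 <- floor(sr); fr <- sr - r0; r1 <- pmin(r0 + 1, Hp)
    c0 <- floor(sc); fc <- sc - c0; c1 <- pmin(c0 + 1, Wp)
    i00 <- r0 + (c0 - 1) * Hp; i01 <- r0 + (c1 - 1) * Hp
    i10 <- r1 + (c0 - 1) * Hp; i11 <- r1 + (c1 - 1) * Hp
    samp <- Xpm[i00, , drop = FALSE] * ((1 - fr) * (1 - fc)) +
            Xpm[i01, , drop = FALSE] * ((1 - fr) * fc) +
            Xpm[i10, , drop = FALSE] * (fr * (1 - fc)) +
            Xpm[i11, , drop = FALSE] * (fr * fc)
    O <- O + samp %*% matrix(wv[i, j, , ], cin, cout)
    cache[[tap]] <- list(i00 = i00, i01 = i01, i10 = i10, i11 = i11,
                         fr = fr, fc = fc, samp = samp,
                         in_r = sr_raw >= 1 & sr_raw <= Hp,
                         in_c = sc_raw >= 1 & sc_raw <= Wp)
  }
  v <- array(O, c(Ho, Wo, cout))
  op_record(ctx, list(x, w, b, offsets), v, function(g) {
    gm <- matrix(g, n_out, cout)
    db <- colSums(gm)
    dW <- array(0, dw)
    dxp_m <- matrix(0, Hp * Wp, cin)
    doff <- array(0, dim(ov))
    for (i in seq_len(kh)) for (j in seq_len(kw)) {
      tap <- (i - 1L) * kw + j
      cc <- cache[[tap]]
      Wm <- matrix(wv[i, j, , ], cin, cout)
      dW[i, j, , ] <- crossprod(cc$samp, gm)
      dS <- gm %*% t(Wm)                       # n_out x cin
      for (corner in list(list(cc$i00, (1 - cc$fr) * (1 - cc$fc)),
                          list(cc$i01, (1 - cc$fr) * cc$fc),
                          list(cc$i10, cc$fr * (1 - cc$fc)),
                          list(cc$i11, cc$fr * cc$fc))) {
        contrib <- dS * corner[[2]]
        acc <- rowsum(contrib, group = corner[[1]])
        u <- as.integer(rownames(acc))
        dxp_m[u, ] <- dxp_m[u, , drop = FALSE] + acc
      }
      x00 <- Xpm[cc$i00, , drop = FALSE]; x01 <- Xpm[cc$i01, , drop = FALSE]
      x10 <- Xpm[cc$i10, , drop = FALSE]; x11 <- Xpm[cc$i11, , drop = FALSE]
      d_dr <- (x10 - x00) * (1 - cc$fc) + (x11 - x01) * cc$fc
      d_dc <- (x01 - x00) * (1 - cc$fr) + (x11 - x10) * cc$fr
      doff[, , 2L * tap - 1L] <- matrix(rowSums(dS * d_dr) * cc$in_r, Ho, Wo)
      doff[, , 2L * tap]      <- matrix(rowSums(dS * d_dc) * cc$in_c, Ho, Wo)
    }
    dxp <- array(dxp_m, c(Hp, Wp, cin))
    dx <- if (pad > 0L)
      dxp[(pad + 1):(pad + H), (pad + 1):(pad + W), , drop = FALSE]
    else dxp
    list(dx, dW, db, doff)
  })
}

## ---- batch normalisation --------------------------------------------------

## per-channel BN over the spatial dimensions of a single image;
## `state` carries running mean/var for eval mode
nd_bn <- function(ctx, x, gamma, beta, state, training,
                  momentum = 0.1, eps = 1e-5) {
  xv <- val(x); gv <- val(gamma); bv <- val(beta)
  d <- dim(xv); N <- d[1] * d[2]; C <- d[3]
  xm <- matrix(xv, N, C)
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu)
    va <- colMeans(xc * xc)
    state$rm <- (1 - momentum) * state$rm + momentum * mu
    state$rv <- (1 - momentum) * state$rv + momentum * va
  } else {
    mu <- state$rm
    xc <- sweep(xm, 2, mu)
    va <- state$rv
  }
  sd_ <- sqrt(va + eps)
  xhat <- sweep(xc, 2, sd_, "/")
  v <- array(sweep(sweep(xhat, 2, gv, "*"), 2, bv, "+"), d)
  op_record(ctx, list(x, gamma, beta), v, function(g) {
    gmat <- matrix(g, N, C)
    dgamma <- colSums(gmat * xhat)
    dbeta <- colSums(gmat)
    dxhat <- sweep(gmat, 2, gv, "*")
    if (training) {
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * xhat)
      dx <- sweep(dxhat, 2, s1 / N) - sweep(xhat, 2, s2 / N, "*")
      dx <- sweep(dx, 2, sd_, "/")
    } else {
      dx <- sweep(dxhat, 2, sd_, "/")
    }
    list(array(dx, d), dgamma, dbeta)
  })
}
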