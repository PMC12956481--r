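# finite-difference verification of the reverse-mode engine
ns <- asNamespace("pointseg")

grad_check <- function(build, x0, tol = 1e-6) {
  ctx <- ns$ctx_new(TRUE)
  xn <- ns$node_new(ctx, x0)
  loss <- build(ctx, xn)
  ns$backward(ctx, loss)
  gn <- num_grad(function(x) ns$val(build(ns$ctx_new(TRUE), x)), x0)
  expect_lt(max(abs(xn$g - gn)) / max(1e-8, max(abs(gn))), tol)
}

test_that("convolution gradients match finite differences", {
  set.seed(1)
  w <- array(rnorm(3 * 3 * 2 * 3) * 0.5, c(3, 3, 2, 3)); b <- rnorm(3) * 0.1
  x0 <- array(rnorm(6 * 8 * 2), c(6, 8, 2))
  wgt <- array(seq_len(6 * 8 * 3) / 100, c(6, 8, 3))
  grad_check(function(ctx, x)
    ns$nd_sum(ctx, ns$nd_mul(ctx, ns$nd_conv2d(ctx, x, w, b), wgt)), x0)
  grad_check(function(ctx, x)
    ns$nd_mean(ctx, ns$nd_conv2d(ctx, x, w, b, stride = 2L)), x0)
  x16 <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  grad_check(function(ctx, x)
    ns$nd_mean(ctx, ns$nd_conv2d(ctx, x, w, b, dilation = 2L)), x16)

  # weight and bias gradients
  ctx <- ns$ctx_new(TRUE); wn <- ns$node_new(ctx, w)
  ns$backward(ctx, ns$nd_mean(ctx, ns$nd_conv2d(ctx, x0, wn, b)))
  gn <- num_grad(function(ww)
    ns$val(ns$nd_mean(ns$ctx_new(TRUE), ns$nd_conv2d(ns$ctx_new(TRUE), x0, ww, b))), w)
  expect_lt(max(abs(wn$g - gn)) / max(abs(gn)), 1e-6)
})

test_that("deformable convolution with zero offsets equals standard convolution", {
  set.seed(2)
  for (rep in 1:3) {
    x <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
    w <- array(rnorm(3 * 3 * 4 * 5) * 0.3, c(3, 3, 4, 5))
    b <- rnorm(5) * 0.1
    off0 <- array(0, c(16, 16, 18))
    plain <- ns$nd_conv2d(ns$ctx_new(FALSE), x, w, b)
    deform <- ns$nd_dconv2d(ns$ctx_new(FALSE), x, w, b, off0)
    expect_lt(max(abs(plain - deform)), 1e-5)
  }
})

test_that("deformable convolution gradients (input and offsets) match finite differences", {
  set.seed(3)
  w <- array(rnorm(3 * 3 * 2 * 2) * 0.5, c(3, 3, 2, 2)); b <- rnorm(2) * 0.1
  x0 <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  offr <- array(rnorm(6 * 6 * 18) * 0.3, c(6, 6, 18))
  grad_check(function(ctx, x)
    ns$nd_mean(ctx, ns$nd_dconv2d(ctx, x, w, b, offr)), x0, tol = 1e-5)
  ctx <- ns$ctx_new(TRUE); on <- ns$node_new(ctx, offr)
  ns$backward(ctx, ns$nd_mean(ctx, ns$nd_dconv2d(ctx, x0, w, b, on)))
  gn <- num_grad(function(o)
    ns$val(ns$nd_mean(ns$ctx_new(TRUE), ns$nd_dconv2d(ns$ctx_new(TRUE), x0, w, b, o))), offr)
  expect_lt(max(abs(on$g - gn)) / max(abs(gn)), 1e-5)
})

test_that("batchnorm, resize, pooling and attention ops backpropagate correctly", {
  set.seed(4)
  x0 <- array(rnorm(6 * 8 * 2), c(6, 8, 2))
  gam <- rnorm(2) * 0.5 + 1; bet <- rnorm(2) * 0.1
  grad_check(function(ctx, x) {
    st <- new.env(); st$rm <- numeric(2); st$rv <- rep(1, 2)
    wgt <- array(seq_len(96) / 10, c(6, 8, 2))
    ns$nd_mean(ctx, ns$nd_mul(ctx, ns$nd_bn(ctx, x, gam, bet, st, TRUE), wgt))
  }, x0, tol = 1e-5)
  wgt2 <- array(seq_len(9 * 13 * 2) / 50, c(9, 13, 2))
  grad_check(function(ctx, x)
    ns$nd_mean(ctx, ns$nd_mul(ctx, ns$nd_resize(ctx, x, 9, 13), wgt2)), x0)
  x16 <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  grad_check(function(ctx, x) ns$nd_mean(ctx, ns$nd_avgpool2(ctx, x)), x16)
  grad_check(function(ctx, x)
    ns$nd_sum(ctx, ns$nd_add(ctx, ns$nd_spatial_max(ctx, x),
                             ns$nd_spatial_mean(ctx, x))), x0)
  grad_check(function(ctx, x)
    ns$nd_mean(ctx, ns$nd_concat_c(ctx, ns$nd_channel_max(ctx, x),
                                   ns$nd_channel_mean(ctx, x))), x0)
})

test_that("a CBAM block backpropagates and attenuates its input", {
  set.seed(5)
  blk <- ns$with_seed(5, ns$layer_cbam(2L))
  x0 <- array(rnorm(6 * 8 * 2), c(6, 8, 2))
  grad_check(function(ctx, x) ns$nd_mean(ctx, ns$fw_cbam(ctx, blk, x)), x0,
             tol = 1e-5)
  out <- cbam(x0, block = blk)
  expect_true(all(abs(out) <= abs(x0) + 1e-12))  # weights in (0,1)
  # spatially constant input -> constant spatial attention away from the
  # zero-padded border of the 7x7 spatial-attention convolution
  xc <- array(rep(c(0.3, -0.7), each = 196), c(14, 14, 2))
  oc <- cbam(xc, block = blk)
  inner <- oc[4:11, 4:11, , drop = FALSE]
  expect_lt(max(abs(sweep(inner, 3, inner[1, 1, ]))), 1e-12)
})

test_that("decoder block routes gradient to both inputs", {
  set.seed(6)
  blk <- ns$with_seed(6, ns$layer_decoder_block(2L, 2L, 2L))
  reset_bn <- function() for (nm in c("bn1", "bn2")) {
    blk[[nm]]$state$rm[] <- 0; blk[[nm]]$state$rv[] <- 1
  }
  x0 <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  sk <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  run <- function(up, skp, train = TRUE) {
    reset_bn()
    ctx <- ns$ctx_new(train)
    upn <- ns$node_new(ctx, up); skn <- ns$node_new(ctx, skp)
    L <- ns$nd_mean(ctx, ns$fw_decoder_block(ctx, blk, upn, skn))
    list(L = L, up = upn, sk = skn, ctx = ctx)
  }
  r <- run(x0, sk); ns$backward(r$ctx, r$L)
  gn_up <- num_grad(function(x) ns$val(run(x, sk)$L), x0)
  gn_sk <- num_grad(function(x) ns$val(run(x0, x)$L), sk)
  expect_lt(max(abs(r$up$g - gn_up)) / max(abs(gn_up)), 1e-5)
  expect_lt(max(abs(r$sk$g - gn_sk)) / max(abs(gn_sk)), 1e-5)
  expect_error(decoder_block(array(0, c(4, 4, 2)), array(0, c(8, 8, 2))),
               "incompatible")
})

test_that("zero skip features reduce the decoder block to the conv stack", {
  blk <- ns$with_seed(7, ns$layer_decoder_block(2L, 2L, 2L))
  up <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  zero_sk <- array(0, c(4, 4, 2))
  a <- decoder_block(up, zero_sk, block = blk)
  # manual conv stack on the transformed upper features
  ctx <- ns$ctx_new(FALSE)
  t_ <- ns$fw_conv(ctx, blk$transform, up)
  h <- ns$nd_relu(ctx, ns$fw_bn(ctx, blk$bn1, ns$fw_conv(ctx, blk$conv1, t_)))
  h <- ns$nd_relu(ctx, ns$fw_bn(ctx, blk$bn2, ns$fw_conv(ctx, blk$conv2, h)))
  b <- ns$fw_conv(ctx, blk$conv3, h)
  expect_equal(a, b, tolerance = 1e-12)
})
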