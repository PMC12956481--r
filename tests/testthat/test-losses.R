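test_that("segmentation loss matches hand-evaluated cross-entropy", {
  expect_equal(seg_loss(matrix(0.8, 1, 1), matrix(1, 1, 1), matrix(1L, 1, 1)),
               -log(0.8), tolerance = 1e-9)
  expect_lte(seg_loss(matrix(1, 3, 3), matrix(1, 3, 3), matrix(1L, 3, 3)), 1e-6)
  # zero attention mask with background labels: the masked product is 0
  expect_lte(seg_loss(matrix(runif(9), 3, 3), matrix(0, 3, 3),
                      matrix(0L, 3, 3)), 1e-6)
  expect_error(seg_loss(matrix(0.5, 2, 2), matrix(1, 2, 2),
                        matrix(255L, 2, 2)), "unlabeled")
})

test_that("attention loss matches the printed partial loss and is linear in alpha", {
  yv <- matrix(255L, 2, 2)
  yv[1, 1] <- 1L; yv[1, 2] <- 1L; yv[2, 1] <- 0L   # 2 positives, 1 negative
  f <- matrix(0.5, 2, 2)
  expect_equal(att_loss(f, yv, alpha = 0.4), 0.7, tolerance = 1e-9)
  expect_equal(att_loss(f, yv, alpha = 0.8), 0.9, tolerance = 1e-9)
  perfect <- matrix(1, 2, 2)
  expect_equal(att_loss(perfect, yv, alpha = 0.4), 0, tolerance = 1e-12)
  # alternative reading: ridge pixels pushed towards 0
  expect_equal(att_loss(f, yv, alpha = 0.4, neg_target = 0), 0.7,
               tolerance = 1e-9)  # |0.5| = |1 - 0.5| at f = 0.5
  expect_equal(att_loss(matrix(1, 2, 2), yv, alpha = 0.4, neg_target = 0),
               0.4, tolerance = 1e-9)
  only_pos <- matrix(255L, 2, 2); only_pos[1, 1] <- 1L
  expect_error(att_loss(f, only_pos), "negative")
  only_neg <- matrix(255L, 2, 2); only_neg[1, 1] <- 0L
  expect_error(att_loss(f, only_neg), "positive")
})

test_that("constraint loss is the channel-averaged L1 and is channel-symmetric", {
  h <- array(c(0.5, 0.9), c(1, 1, 2))
  expect_equal(cons_loss(matrix(0.8, 1, 1), h), 0.2, tolerance = 1e-9)
  hp <- array(c(0.9, 0.5), c(1, 1, 2))
  expect_equal(cons_loss(matrix(0.8, 1, 1), hp), 0.2, tolerance = 1e-9)
  same <- array(0.3, c(2, 2, 3))
  expect_equal(cons_loss(matrix(0.3, 2, 2), same), 0, tolerance = 1e-12)
})

test_that("total loss combines components with the reference weights", {
  w <- loss_weights()   # 0.4, 0.8, 1, 0.4
  expect_equal(total_loss(0.5, 0.7, 0.2, w), 1.18, tolerance = 1e-9)
  expect_equal(total_loss(0, 0, 0, w), 0)
  # monotone non-decreasing in each component
  expect_gte(total_loss(0.6, 0.7, 0.2, w), total_loss(0.5, 0.7, 0.2, w))
  expect_gte(total_loss(0.5, 0.8, 0.2, w), total_loss(0.5, 0.7, 0.2, w))
  expect_gte(total_loss(0.5, 0.7, 0.3, w), total_loss(0.5, 0.7, 0.2, w))
  expect_error(loss_weights(alpha = -1), ">= 0")
})

test_that("detaching isolates gradients between branches", {
  ns <- asNamespace("pointseg")
  set.seed(8)
  # toy: pred from a 'seg' parameter, f_att from an 'att' parameter
  y <- matrix(1L, 2, 2)
  run <- function(att_shift, detach) {
    seg_p <- ns$ps_param(array(0.2, c(2, 2, 1)))
    ctx <- ns$ctx_new(TRUE)
    pred <- ns$nd_sigmoid(ctx, ns$nd_param(ctx, seg_p))
    f_att <- matrix(0.6 + att_shift, 2, 2)       # acts as AttNet output value
    L <- seg_loss(pred, if (detach) f_att else f_att, y, ctx = ctx)
    ns$backward(ctx, L)
    seg_p$g
  }
  # with the mask detached, perturbing the attention branch's weights (here,
  # its output value) changes seg_loss's gradient only through the mask value
  g0 <- run(0, TRUE); g1 <- run(0, TRUE)
  expect_identical(g0, g1)

  # full training step honours the detach flag: attention parameters receive
  # no gradient from the segmentation loss, constraint parameters none from it
  sc <- generate_scene(64, 64, 4, seed = 3)
  spl <- make_superpixel_label(sc$image, sc$points)
  vl <- make_voronoi_label(sc$points)
  cfg <- train_config(epochs = 1, net = net_config("tiny"),
                      loss_weights = loss_weights(beta = 0.8, gamma = 0, delta = 0))
  m <- joint_model(cfg$net)
  ns$zero_grads(ns$collect_params(m))
  ns$weak_step(m, sc$image, vl$label, spl$label, cfg, training = TRUE)
  att_g <- max(vapply(ns$collect_params(m$att), function(p) max(abs(p$g)), 1))
  cons_g <- max(vapply(ns$collect_params(m$cons), function(p) max(abs(p$g)), 1))
  seg_g <- max(vapply(ns$collect_params(m$seg), function(p) max(abs(p$g)), 1))
  expect_equal(att_g, 0)   # gamma = 0 and mask detached
  expect_equal(cons_g, 0)  # delta = 0 and f_cons/pred detached
  expect_gt(seg_g, 0)
})
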