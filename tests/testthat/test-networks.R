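# shape/range contracts of the three networks (tiny configs, eval mode)
cfg <- net_config("tiny")

test_that("segmentation forward obeys the shape/range contract and the f_cons identity", {
  m <- joint_model(cfg)
  img <- tiny_scene()$image
  p <- segnet_forward(m$seg, img)
  expect_equal(dim(p), c(64L, 64L))
  expect_true(all(p >= 0 & p <= 1))
  # zero f_cons behaves as if absent (additive identity)
  fc <- consnet_forward(m$cons, img)$f_cons
  expect_identical(segnet_forward(m$seg, img, f_cons = array(0, dim(fc))), p)
  # deterministic in eval mode
  expect_identical(segnet_forward(m$seg, img), p)
  # shape mismatch names both shapes
  expect_error(segnet_forward(m$seg, img, f_cons = array(0, c(2, 2, 2))),
               "2x2x2.*16x16x16")
})

test_that("non-multiple-of-16 inputs are padded internally and cropped back", {
  m <- seg_net(cfg)
  img <- generate_scene(70, 45, 3, seed = 2,
                        axis_range = c(2, 4))$image
  p <- segnet_forward(m, img)
  expect_equal(dim(p), c(70L, 45L))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("attention forward takes the 4-channel input and rejects tri-state labels", {
  m <- att_net(cfg)
  sc <- tiny_scene()
  spl <- make_superpixel_label(sc$image, sc$points)
  a <- attnet_forward(m, sc$image, spl$label)
  expect_equal(dim(a), c(64L, 64L))
  expect_true(all(a >= 0 & a <= 1))
  expect_identical(attnet_forward(m, sc$image, spl$label), a)
  bad <- spl$label; bad[1, 1] <- 255L
  expect_error(attnet_forward(m, sc$image, bad), "unlabeled code")
  # the label plane matters: flipping it changes the output
  expect_false(identical(attnet_forward(m, sc$image, 1L - spl$label), a))
})

test_that("constraint network emits f_cons at the encoder-1 shape and an N-channel h", {
  m <- joint_model(cfg)
  img <- tiny_scene()$image
  out <- consnet_forward(m$cons, img)
  expect_equal(dim(out$f_cons), c(16L, 16L, cfg$seg_channels[2]))
  expect_equal(dim(out$h), c(64L, 64L, cfg$consnet_n))
  expect_true(all(out$h >= 0 & out$h <= 1))
  # f_cons merges without error into the segmentation encoder
  p <- segnet_forward(m$seg, img, f_cons = out$f_cons)
  expect_equal(dim(p), c(64L, 64L))
})

test_that("checkpoints round-trip through disk", {
  withr::with_tempdir({
    m <- joint_model(cfg, seeds = c(4L, 5L, 6L))
    img <- tiny_scene()$image
    p <- predict_mask(m, img)
    save_checkpoint(m, "ck.rds")
    m2 <- load_checkpoint("ck.rds")
    expect_identical(predict_mask(m2, img), p)
    expect_identical(predict_mask("ck.rds", img), p)
  })
})
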