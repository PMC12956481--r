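test_that("identity config returns inputs unchanged", {
  sc <- tiny_scene()
  a <- augment(sc$image, list(sc$gt_mask), sc$points, ops = list(), seed = 1)
  expect_identical(a$image, sc$image)
  expect_identical(a$label_maps[[1]], sc$gt_mask)
  expect_identical(a$points$coords, sc$points$coords)
  expect_equal(a$n_dropped, 0L)
})

test_that("horizontal flip reflects point columns", {
  ps <- point_set(rbind(c(10, 3)), c(64, 64))
  a <- augment(tiny_scene()$image, list(), ps, ops = list(hflip = 1), seed = 1)
  expect_equal(unname(a$points$coords[1, ]), c(10L, 60L))
})

test_that("affine-transformed label maps contain only coded values", {
  sc <- tiny_scene()
  vl <- make_voronoi_label(sc$points, r_pt = 2)
  for (s in 1:8) {
    a <- suppressMessages(augment(
      sc$image, list(vl$label, sc$gt_mask), sc$points,
      ops = list(affine = list(rotation = 30, scale = c(0.8, 1.2), shear = 10)),
      seed = s))
    expect_true(all(a$label_maps[[1]] %in% c(0L, 1L, 255L)))
    expect_true(all(a$label_maps[[2]] %in% c(0L, 1L)))
  }
})

test_that("points stay inside their identically transformed instance masks", {
  ops <- list(hflip = 0.5, vflip = 0.5,
              affine = list(rotation = 30, scale = c(0.8, 1.2), shear = 10))
  for (s in 1:10) {
    sc <- generate_scene(64, 64, 5, seed = s)
    a <- suppressMessages(augment(sc$image, sc$instance_masks, sc$points,
                                  ops = ops, seed = s + 100))
    union_mask <- Reduce(pmax, a$label_maps)
    pp <- a$points$coords
    if (nrow(pp)) expect_true(all(union_mask[pp + 1L] == 1L))
  }
})

test_that("augmentation is deterministic per seed and photometric ops leave geometry alone", {
  sc <- tiny_scene()
  ops <- list(hflip = 0.5, blur = list(prob = 1, sigma = c(0.5, 1.5)),
              hue = 0.05, saturation = 0.2)
  a1 <- augment(sc$image, list(sc$gt_mask), sc$points, ops, seed = 11)
  a2 <- augment(sc$image, list(sc$gt_mask), sc$points, ops, seed = 11)
  expect_identical(a1, a2)

  photometric <- list(blur = list(prob = 1, sigma = c(1, 1)), hue = 0.05)
  b <- augment(sc$image, list(sc$gt_mask), sc$points, photometric, seed = 3)
  expect_identical(b$label_maps[[1]], sc$gt_mask)
  expect_identical(b$points$coords, sc$points$coords)
  expect_false(identical(b$image, sc$image))
})
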