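test_that("scene generation is deterministic and honours nucleus counts", {
  a <- generate_scene(64, 64, 5, seed = 7)
  b <- generate_scene(64, 64, 5, seed = 7)
  expect_identical(a, b)
  expect_length(a$instance_masks, 5L)
  expect_equal(length(a$points), 5L)

  empty <- generate_scene(64, 64, 0, seed = 1)
  expect_true(all(empty$gt_mask == 0L))
  expect_equal(length(empty$points), 0L)
})

test_that("every centroid lies inside its own instance mask", {
  sc <- generate_scene(96, 96, 10, seed = 3)
  p <- sc$points$coords
  for (k in seq_len(nrow(p)))
    expect_equal(sc$instance_masks[[k]][p[k, 1] + 1, p[k, 2] + 1], 1L)
})

test_that("gt mask is the union of instances and foreground is proper", {
  for (s in 1:5) {
    sc <- generate_scene(64, 64, 4, seed = s)
    un <- Reduce(pmax, sc$instance_masks)
    expect_identical(sc$gt_mask, un)
    fg <- mean(sc$gt_mask)
    expect_gt(fg, 0); expect_lt(fg, 1)
  }
})

test_that("placement failure under no-overlap is reported", {
  expect_error(generate_scene(32, 32, 400, seed = 1, overlap_allowed = FALSE),
               "placement failed")
})

test_that("dataset generation is deterministic and respects the count range", {
  d1 <- withr::with_tempdir({
    generate_dataset(4, 64, 64, c(2, 6), seed = 0, dir = "ds")
    list(files = list.files("ds", recursive = TRUE),
         img = png::readPNG("ds/images/img001.png"),
         pts = read.csv("ds/points/img002.csv"))
  })
  d2 <- withr::with_tempdir({
    generate_dataset(4, 64, 64, c(2, 6), seed = 0, dir = "ds")
    list(files = list.files("ds", recursive = TRUE),
         img = png::readPNG("ds/images/img001.png"),
         pts = read.csv("ds/points/img002.csv"))
  })
  expect_identical(d1, d2)

  scenes <- generate_dataset(4, 64, 64, c(2, 6), seed = 0)
  counts <- vapply(scenes, function(s) length(s$points), 1L)
  expect_true(all(counts >= 2 & counts <= 6))
  one <- generate_dataset(1, 64, 64, c(3, 3), seed = 0)
  expect_equal(length(one[[1]]$points), 3L)
})
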