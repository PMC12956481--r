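test_that("a single point owns the whole frame", {
  ps <- point_set(rbind(c(5, 20)), c(32, 32))
  expect_true(all(voronoi_partition(ps) == 0L))
  vl <- make_voronoi_label(ps, r_pt = 2)
  expect_equal(sum(vl$label == 0L), 0L)        # no ridge, no negatives
  expect_gt(sum(vl$label == 1L), 0L)
})

test_that("two points on a 1 x 32 strip split at the midpoint with ridge at the boundary", {
  ps <- point_set(rbind(c(0, 0), c(0, 31)), c(1, 32))
  v <- voronoi_partition(ps)
  expect_true(all(v[1, 1:16] == 0L))
  expect_true(all(v[1, 17:32] == 1L))
  vl <- make_voronoi_label(ps, r_pt = 0, ridge_width = 1)
  expect_equal(which(vl$label[1, ] == 0L), c(16L, 17L))  # boundary columns
  expect_equal(sum(vl$label == 1L), 2L)                  # r_pt = 0: the points
})

test_that("the partition matches the brute-force nearest-point oracle", {
  for (s in 1:6) {
    n <- sample(1:10, 1)
    coords <- unique(cbind(sample(0:63, n, TRUE), sample(0:63, n, TRUE)))
    ps <- point_set(coords, c(64, 64))
    expect_identical(voronoi_partition(ps), voronoi_brute(ps, c(64, 64)))
  }
})

test_that("each Voronoi cell contains exactly one point and the tri-state partition is exhaustive", {
  set.seed(42)
  sc <- generate_scene(64, 64, 8, seed = 5)
  vl <- make_voronoi_label(sc$points, r_pt = 2)
  cells <- vl$cell_index[sc$points$coords + 1L]
  expect_equal(sort(unique(c(vl$cell_index))), 0:(length(sc$points) - 1))
  expect_equal(sort(cells), 0:(length(sc$points) - 1))  # one point per cell
  expect_true(all(vl$label %in% c(0L, 1L, 255L)))
  pos <- vl$label == 1L; neg <- vl$label == 0L
  expect_equal(sum(pos & neg), 0L)
})

test_that("degenerate inputs are rejected", {
  ps <- point_set(NULL, c(16, 16))
  expect_error(voronoi_partition(ps), "at least one point")
  good <- point_set(rbind(c(1, 1)), c(16, 16))
  expect_error(make_voronoi_label(good, r_pt = -1), "r_pt")
})
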