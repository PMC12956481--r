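test_that("overlap metrics honour their identities", {
  m <- matrix(0L, 8, 8); m[2:5, 2:5] <- 1L
  expect_equal(iou_score(m, m), 1)
  expect_equal(dice_score(m, m), 1)
  disj <- matrix(0L, 8, 8); disj[7:8, 7:8] <- 1L
  expect_equal(iou_score(m, disj), 0)
  expect_equal(dice_score(m, disj), 0)
  # |A| = |B| = 4, |A n B| = 2
  a <- matrix(0L, 4, 4); a[1, 1:4] <- 1L
  b <- matrix(0L, 4, 4); b[1, 3:4] <- 1L; b[2, 1:2] <- 1L
  expect_equal(iou_score(a, b), 1 / 3)
  expect_equal(dice_score(a, b), 1 / 2)
})

test_that("Dice = 2 IoU / (1 + IoU) on random masks", {
  set.seed(9)
  for (rep in 1:20) {
    a <- matrix(rbinom(64, 1, 0.4), 8, 8)
    b <- matrix(rbinom(64, 1, 0.4), 8, 8)
    i <- iou_score(a, b)
    expect_equal(dice_score(a, b), 2 * i / (1 + i), tolerance = 1e-12)
  }
})

test_that("evaluate_model scores thresholded predictions against masks on disk", {
  withr::with_tempdir({
    dir.create("images"); dir.create("masks")
    scenes <- generate_dataset(2, 64, 64, c(3, 5), seed = 4)
    for (id in names(scenes)) {
      write_image(scenes[[id]]$image, file.path("images", paste0(id, ".png")))
      write_mask(scenes[[id]]$gt_mask, file.path("masks", paste0(id, ".png")))
    }
    m <- joint_model(net_config("tiny"))
    df <- evaluate_model(m, "images", "masks", out_prefix = "metrics")
    expect_equal(nrow(df), 2L)
    expect_true(all(df$iou >= 0 & df$iou <= 1))
    expect_true(all(abs(df$dice - 2 * df$iou / (1 + df$iou)) < 1e-12))
    expect_true(file.exists("metrics.json"))
    js <- jsonlite::read_json("metrics.json")
    expect_equal(js$mean$iou, attr(df, "mean")[["iou"]], tolerance = 1e-9)

    # shape mismatch is reported
    write_mask(matrix(0L, 32, 32), file.path("masks", "img001.png"))
    expect_error(evaluate_model(m, "images", "masks"), "disagree on shape")
  })
})
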