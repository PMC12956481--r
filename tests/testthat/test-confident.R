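# the worked 5-pixel example used throughout:
# labels (1,1,0,0,0), foreground probabilities (.9,.2,.1,.8,.3)
worked_ds <- function() {
  p1 <- c(0.9, 0.2, 0.1, 0.8, 0.3)
  pixel_dataset(cbind(1 - p1, p1), c(1L, 1L, 0L, 0L, 0L))
}

test_that("class thresholds are per-class mean self-confidences", {
  ds <- worked_ds()
  t <- class_thresholds(ds)
  expect_equal(t, c(0.6, 0.55), tolerance = 1e-12)
  # invariant to pixel order
  perm <- c(3, 1, 5, 2, 4)
  dsp <- pixel_dataset(ds$probs[perm, ], ds$labels[perm])
  expect_equal(class_thresholds(dsp), t)
  # one-hot correct predictions give t = (1, 1)
  oh <- pixel_dataset(cbind(c(1, 0), c(0, 1)), c(0L, 1L))
  expect_equal(class_thresholds(oh), c(1, 1))
  # missing class errors
  expect_error(class_thresholds(pixel_dataset(cbind(1, 0), 0L)), "label 1")
})

test_that("the counting matrix matches the worked example and the t = 1 edge case", {
  ds <- worked_ds()
  C <- counting_matrix(ds, class_thresholds(ds))
  expect_equal(unname(unclass(C)), matrix(c(2L, 1L, 1L, 1L), 2, 2))
  expect_lte(sum(C), length(ds$labels))
  # perfectly confident predictions with t = (1,1): >= relaxation keeps them
  oh <- pixel_dataset(cbind(c(1, 0, 1), c(0, 1, 0)), c(0L, 1L, 0L))
  Coh <- counting_matrix(oh, class_thresholds(oh))
  expect_equal(unname(unclass(Coh)), matrix(c(2L, 0L, 0L, 1L), 2, 2))
})

test_that("the counting matrix equals the naive per-pixel loop on random datasets", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(c(50L, 500L, 10000L), 1)
    p1 <- runif(n)
    labels <- rbinom(n, 1, 0.4)
    ds <- pixel_dataset(cbind(1 - p1, p1), labels)
    t <- class_thresholds(ds)
    expect_identical(unname(unclass(counting_matrix(ds, t))),
                     counting_brute(ds$probs, labels, t))
  }
})

test_that("the joint distribution is the calibrated, normalised counting matrix", {
  ds <- worked_ds()
  Q <- joint_distribution(counting_matrix(ds, class_thresholds(ds)), ds)
  expect_equal(unname(unclass(Q)), matrix(c(0.4, 0.2, 0.2, 0.2), 2, 2),
               tolerance = 1e-12)
  expect_equal(sum(Q), 1, tolerance = 1e-9)
  # row sums proportional to label frequencies
  expect_equal(unname(rowSums(Q)), c(0.6, 0.4), tolerance = 1e-12)
  zeroC <- matrix(c(0L, 1L, 0L, 1L), 2, 2)   # first row all zero
  expect_error(joint_distribution(zeroC, ds), "empty row")
})

test_that("correction flips exactly the margin-ranked pixels of the worked example", {
  ds <- worked_ds()
  Q <- joint_distribution(counting_matrix(ds, class_thresholds(ds)), ds)
  cor <- correct_labels(ds, Q)
  expect_equal(cor$labels, c(1L, 0L, 0L, 1L, 0L))
  expect_equal(which(cor$flipped), c(2L, 4L))
  # strictly diagonal Q flips nothing
  none <- correct_labels(ds, diag(c(0.6, 0.4)))
  expect_equal(none$labels, ds$labels)
  expect_false(any(none$flipped))
})

test_that("one-hot true-class probabilities recover all injected flips", {
  set.seed(23)
  for (rep in 1:5) {
    n <- 2000L
    y_true <- rbinom(n, 1, 0.4)
    y_noisy <- y_true
    k <- 25L
    f0 <- sample(which(y_true == 0), k); f1 <- sample(which(y_true == 1), k)
    y_noisy[f0] <- 1L; y_noisy[f1] <- 0L
    ds <- pixel_dataset(cbind(1 - y_true, y_true), y_noisy)
    Q <- joint_distribution(counting_matrix(ds, class_thresholds(ds)), ds)
    cor <- correct_labels(ds, Q)
    expect_identical(cor$labels, y_true)
    expect_equal(sum(cor$flipped), 2L * k)
  }
})

test_that("calibrated noisy probabilities recover more injected flips than they break", {
  # well-calibrated model: probability of the true class ~ Beta(8, 2);
  # 10% of labels flipped. Recovery must beat the false-flip rate in
  # every replicate.
  for (s in 1:20) {
    set.seed(1000 + s)
    n <- 4000L
    y_true <- rbinom(n, 1, 0.35)
    conf <- rbeta(n, 8, 2)
    p_true <- ifelse(y_true == 1, conf, 1 - conf)
    flip <- sample(n, round(0.1 * n))
    y_noisy <- y_true
    y_noisy[flip] <- 1L - y_noisy[flip]
    ds <- pixel_dataset(cbind(1 - p_true, p_true), y_noisy)
    Q <- joint_distribution(counting_matrix(ds, class_thresholds(ds)), ds)
    cor <- correct_labels(ds, Q)
    recovered <- mean(cor$labels[flip] == y_true[flip])
    clean <- setdiff(seq_len(n), flip)
    false_flip <- mean(cor$flipped[clean])
    expect_gt(recovered, false_flip)
  }
})

test_that("refine_dataset composes the steps and reports flip fractions", {
  set.seed(5)
  H <- 20L; W <- 20L
  mk <- function() {
    gt <- matrix(rbinom(H * W, 1, 0.3), H, W)
    prob <- matrix(pmin(pmax(gt * 0.8 + 0.1 + rnorm(H * W, 0, 0.05), 0.01), 0.99), H, W)
    ys <- gt
    noise <- sample(H * W, 30)
    ys[noise] <- 1L - ys[noise]
    list(gt = gt, prob = prob, ys = ys)
  }
  d1 <- mk(); d2 <- mk()
  res <- refine_dataset(list(a = d1$prob, b = d2$prob),
                        list(a = d1$ys, b = d2$ys), scope = "per_image")
  expect_named(res$refined, c("a", "b"))
  # label differs from input exactly where the flip mask is set
  expect_identical(res$refined$a != d1$ys, res$flip_masks$a == 1L)
  expect_equal(res$summary$flip_fraction,
               mean(c(res$flip_masks$a, res$flip_masks$b)))
  # per-image scope on one image is the plain four-step chain
  ds <- pixel_dataset(cbind(1 - c(d1$prob), c(d1$prob)), c(d1$ys))
  Q <- joint_distribution(counting_matrix(ds, class_thresholds(ds)), ds)
  direct <- correct_labels(ds, Q)
  expect_identical(c(res$refined$a), direct$labels)
  # pooled scope runs too
  resp <- refine_dataset(list(a = d1$prob, b = d2$prob),
                         list(a = d1$ys, b = d2$ys), scope = "pooled")
  expect_named(resp$refined, c("a", "b"))
})
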