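# Macro metrics, stratified folds, pooled t-tests and the cross-validation
# harness.

test_that("confusion counts match the nested-loop oracle and validate labels", {
  withr::with_seed(1, {
    for (rep in 1:5) {
      yt <- sample(0:4, 50, replace = TRUE)
      yp <- sample(0:4, 50, replace = TRUE)
      got <- confusion_counts(yt, yp, 5)
      ref <- confusion_oracle(yt, yp, 5)
      expect_identical(got$TP, ref$TP)
      expect_identical(got$TN, ref$TN)
      expect_identical(got$FP, ref$FP)
      expect_identical(got$FN, ref$FN)
      expect_true(all(got$TP + got$TN + got$FP + got$FN == 50L))
    }
  })
  # perfect predictions and total inversion
  perf <- confusion_counts(0:4, 0:4, 5)
  expect_true(all(perf$FP == 0L) && all(perf$FN == 0L))
  inv <- confusion_counts(c(0, 0, 1, 1), c(1, 1, 0, 0), 2)
  expect_true(all(inv$TP == 0L) && all(inv$TN == 0L))
  expect_error(confusion_counts(c(0, 5), c(0, 1), 5), "lie in")
  expect_error(confusion_counts(0:2, 0:1, 3), "length")
})

test_that("macro metrics equal the one-vs-rest formula oracle to 1e-12", {
  withr::with_seed(2, {
    for (rep in 1:20) {
      l <- sample(2:6, 1)
      n <- sample(20:80, 1)
      yt <- sample(0:(l - 1), n, replace = TRUE)
      yp <- sample(0:(l - 1), n, replace = TRUE)
      cc <- confusion_counts(yt, yp, l)
      rep_got <- macro_metrics(cc)
      acc <- sen <- spe <- pre <- numeric(l)
      for (i in 1:l) {
        tp <- cc$TP[i]; tn <- cc$TN[i]; fp <- cc$FP[i]; fn <- cc$FN[i]
        acc[i] <- (tp + tn) / (tp + tn + fp + fn)
        sen[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
        spe[i] <- if (fp + tn > 0) tn / (fp + tn) else 0
        pre[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
      }
      expect_equal(rep_got$average_acc, mean(acc), tolerance = 1e-12)
      expect_equal(rep_got$average_sen, mean(sen), tolerance = 1e-12)
      expect_equal(rep_got$average_spe, mean(spe), tolerance = 1e-12)
      expect_equal(rep_got$average_pre, mean(pre), tolerance = 1e-12)
      expect_equal(rep_got$overall_accuracy, mean(yt == yp),
                   tolerance = 1e-12)
    }
  })
  # macro accuracy exceeds overall accuracy for l > 2 (one-vs-rest reading)
  yt <- rep(0:4, each = 10)
  yp <- yt; yp[1:10] <- 1
  r <- macro_metrics(confusion_counts(yt, yp, 5))
  expect_gt(r$average_acc, r$overall_accuracy)
  # a class never predicted: precision undefined -> flagged, contributes 0
  yt2 <- c(0, 0, 1, 1)
  yp2 <- c(0, 0, 0, 0)
  r2 <- macro_metrics(confusion_counts(yt2, yp2, 2))
  expect_true(r2$undefined$pre[2])
  expect_equal(r2$average_pre, (2 / 4 + 0) / 2, tolerance = 1e-12)
  # perfect predictions give all four metrics = 1
  rp <- macro_metrics(confusion_counts(yt, yt, 5))
  expect_equal(c(rp$average_acc, rp$average_sen, rp$average_spe,
                 rp$average_pre), rep(1, 4), tolerance = 1e-12)
})

test_that("stratified folds partition the data with balanced class counts", {
  labels <- rep(0:4, each = 120)
  folds <- stratified_kfold(labels, 5, seed = 3)
  test_sets <- lapply(folds, `[[`, "test")
  expect_identical(sort(unlist(test_sets)), seq_along(labels))
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0L)
    expect_identical(as.vector(table(labels[f$test])), rep(24L, 5))
  }
  expect_identical(folds, stratified_kfold(labels, 5, seed = 3))
  # uneven class sizes: per-fold counts differ by at most one
  lab2 <- rep(0:1, c(23, 11))
  f2 <- stratified_kfold(lab2, 5, seed = 4)
  for (cl in 0:1) {
    counts <- vapply(f2, function(f) sum(lab2[f$test] == cl), integer(1))
    expect_lte(diff(range(counts)), 1L)
  }
  expect_error(stratified_kfold(rep(0:1, c(3, 50)), 5), "fewer than")
})

test_that("pooled t-test matches the textbook formula and stats::t.test", {
  a <- withr::with_seed(5, stats::rnorm(5))
  b <- withr::with_seed(6, stats::rnorm(5, mean = 0.5))
  got <- two_sample_ttest(a, b)
  sp2 <- ((5 - 1) * var(a) + (5 - 1) * var(b)) / 8
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  expect_equal(got$t, t_manual, tolerance = 1e-10)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  # symmetry and the identical-sample case
  expect_equal(two_sample_ttest(b, a)$t, -got$t, tolerance = 1e-12)
  same <- two_sample_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # gross separation is significant
  expect_lt(two_sample_ttest(c(1, 2, 3), c(11, 12, 13))$p, 0.05)
  expect_error(two_sample_ttest(c(1, 1), c(1, 1)), "pooled variance")
  # paired companion
  pt <- paired_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(pt$t, 0)
  expect_equal(pt$p, 1)
  d1 <- withr::with_seed(7, stats::rnorm(10))
  d2 <- d1 + withr::with_seed(8, stats::rnorm(10, 0.3, 0.1))
  ref_p <- stats::t.test(d2, d1, paired = TRUE)
  got_p <- paired_ttest(d2, d1)
  expect_equal(got_p$t, unname(ref_p$statistic), tolerance = 1e-10)
})

test_that("cross-validation with an oracle extractor is perfect and reproducible", {
  # one-hot features indexed by the true class: any prototype classifier
  # built on them is exact
  labels <- rep(0:4, each = 40)
  x <- diag(5)[labels + 1, ]
  ds <- list(x = x, labels = labels)
  proto <- list(k = 5, n = 3, q = 5, episodes_per_fold = 2)
  res <- run_crossval(ds, function(xt, yt, seed) identity, proto, seed = 11)
  expect_equal(res$mean, 1)
  expect_equal(res$sd, 0)
  expect_equal(res$report$average_acc, 1)
  res2 <- run_crossval(ds, function(xt, yt, seed) identity, proto, seed = 11)
  expect_identical(res$episode_accuracy, res2$episode_accuracy)
})
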