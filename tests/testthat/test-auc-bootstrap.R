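# ROC/AUC in ascending orientation and the stratified bootstrap.

test_that("AUC hits its closed-form landmarks", {
  expect_equal(aucFromValues(c(1, 2, 3, 10, 11, 12), rep(0:1, each = 3)), 1)
  expect_equal(aucFromValues(rep(5, 10), rep(0:1, 5)), 0.5)
  # a feature lower in the positive class gives AUC below 0.5 (no flipping)
  expect_equal(aucFromValues(c(10, 11, 12, 1, 2, 3), rep(0:1, each = 3)), 0)
})

test_that("AUC equals all-pairs counting with half credit for ties", {
  v <- c(3, 1, 4, 1, 5, 9); y <- c(0, 0, 1, 1, 0, 1)
  expect_equal(aucFromValues(v, y), oracleAUC(v, y))
  set.seed(6)
  for (i in 1:20) {
    n <- sample(8:30, 1)
    vals <- sample(1:8, n, replace = TRUE)  # many ties
    lab <- sample(rep(0:1, length.out = n))
    if (length(unique(lab)) < 2) next
    expect_equal(aucFromValues(vals, lab), oracleAUC(vals, lab))
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  v <- rnorm(60); y <- rep(0:1, 30)
  ours <- aucFromValues(v, y)
  theirs <- as.numeric(pROC::auc(pROC::roc(y, v, direction = "<",
                                           quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(14)
  v <- rnorm(50); y <- sample(rep(0:1, 25))
  a0 <- aucFromValues(v, y)
  expect_equal(aucFromValues(exp(v), y), a0)
  expect_equal(aucFromValues(v^3 + 2 * v, y), a0)
})

test_that("stratified bootstrap is seeded, preserves proportions and collapses
           for constant statistics", {
  set.seed(20)
  v <- c(rnorm(20, 1), rnorm(25, 0)); y <- rep(1:0, c(20, 25))
  c1 <- stratifiedBootstrapCi(v, y, nBoot = 300, seed = 42)
  c2 <- stratifiedBootstrapCi(v, y, nBoot = 300, seed = 42)
  expect_identical(c1$replicates, c2$replicates)
  expect_lte(c1$ciLow, c1$ciHigh)
  # class proportions preserved in every replicate
  propStat <- function(values, labels) mean(labels)
  cp <- stratifiedBootstrapCi(v, y, statistic = propStat, nBoot = 50, seed = 1)
  expect_equal(unique(cp$replicates), 20 / 45)
  cc <- stratifiedBootstrapCi(v, y, statistic = function(a, b) 0.7,
                              nBoot = 50, seed = 1)
  expect_equal(cc$ciLow, 0.7); expect_equal(cc$ciHigh, 0.7)
  expect_error(stratifiedBootstrapCi(v[1:4], y[1:4]), "at least 3")
})

test_that("bootstrap intervals tighten with sample size", {
  set.seed(33)
  mk <- function(n) list(v = c(rnorm(n, 1), rnorm(n, 0)),
                         y = rep(1:0, each = n))
  d40 <- mk(20); d160 <- mk(80)
  w40 <- with(stratifiedBootstrapCi(d40$v, d40$y, nBoot = 400, seed = 2),
              ciHigh - ciLow)
  w160 <- with(stratifiedBootstrapCi(d160$v, d160$y, nBoot = 400, seed = 2),
               ciHigh - ciLow)
  expect_lt(w160, w40)
})

test_that("univariate logistic AUC reports a full, reproducible result", {
  set.seed(40)
  v <- c(rnorm(45, 0.8), rnorm(45, 0))
  y <- c(rep("DM", 45), rep("non-DM", 45))
  r <- univariateLogisticAuc(v, y, nBoot = 400, seed = 7)
  expect_s3_class(r, "AUCResult")
  expect_true(r$auc > 0.5 && r$auc <= 1)
  expect_true(r$ciLow <= r$auc && r$auc <= r$ciHigh)
  expect_length(r$coef, 2)
  expect_gt(r$coef[2], 0)  # positive slope for the higher-in-DM feature
  r2 <- univariateLogisticAuc(v, y, nBoot = 400, seed = 7)
  expect_equal(r$ciLow, r2$ciLow)
  expect_false(r$degenerate)
  # ROC curve spans the unit square corners
  expect_equal(r$roc$fpr[1], 0); expect_equal(r$roc$tpr[1], 0)
  expect_equal(rev(r$roc$fpr)[1], 1); expect_equal(rev(r$roc$tpr)[1], 1)
  # constant feature: AUC 0.5
  rc <- univariateLogisticAuc(rep(2, 20), rep(0:1, 10), nBoot = 50, seed = 1)
  expect_equal(rc$auc, 0.5)
  expect_true(rc$degenerate)
})

test_that("perfect separation is flagged but the rank-based AUC survives", {
  v <- c(1:10, 101:110); y <- rep(0:1, each = 10)
  r <- univariateLogisticAuc(v, y, nBoot = 50, seed = 3)
  expect_true(r$separationFlag)
  expect_equal(r$auc, 1)
})
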