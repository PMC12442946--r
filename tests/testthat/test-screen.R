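# Biomarker screening statistics.

test_that("pooled t-test reproduces the worked degrees of freedom", {
  set.seed(1)
  r <- twoSampleTTest(rnorm(24), rnorm(24))
  expect_equal(r$df, 46)  # 24 + 24 - 2
  expect_error(twoSampleTTest(1, 1:5), "at least 2")
})

test_that("pooled t-test matches the textbook formula and handles degeneracy", {
  # hand-computed oracle: means 1 and 11, pooled variance 1,
  # t = -10 / sqrt(1 * (1/3 + 1/3)) = -12.24745, df = 4
  r <- twoSampleTTest(c(0, 1, 2), c(10, 11, 12))
  expect_equal(r$t, -10 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(r$df, 4)
  # identical groups
  same <- twoSampleTTest(c(2, 4, 6), c(2, 4, 6))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  # zero variance, unequal means
  inf <- twoSampleTTest(c(5, 5, 5), c(7, 7, 7))
  expect_true(inf$infinite)
  expect_equal(inf$p, 0)
})

test_that("Spearman correlation follows the midrank oracle and is antisymmetric", {
  v <- c(1, 2, 3, 4); y <- c(0, 0, 1, 1)
  r <- spearmanVsLabel(v, y)
  expect_equal(r$rho, oracleSpearman(v, y), tolerance = 1e-12)
  expect_equal(spearmanVsLabel(-v, y)$rho, -r$rho)
  # permutation null: mean rho near zero
  set.seed(4)
  rhos <- replicate(300, {
    spearmanVsLabel(rnorm(20), sample(rep(0:1, 10)))$rho
  })
  expect_lt(abs(mean(rhos)), 0.05)
  expect_equal(spearmanVsLabel(rep(1, 10), rep(0:1, 5))$rho, 0)
  expect_true(spearmanVsLabel(rep(1, 10), rep(0:1, 5))$degenerate)
})

test_that("mutual information separates signal from noise", {
  set.seed(7)
  # independence: MI near 0
  miNull <- mean(replicate(20, mutualInfoScore(rnorm(60), rep(0:1, 30))))
  expect_lt(miNull, 0.06)
  # perfect balanced separation: MI near ln 2 (plug-in oracle H(label))
  v <- c(rnorm(40, 0, 0.2), rnorm(40, 20, 0.2))
  y <- rep(0:1, each = 40)
  expect_equal(mutualInfoScore(v, y), log(2), tolerance = 0.08)
  # invariance under strictly monotone transforms (kNN estimator property)
  set.seed(9)
  v2 <- c(rnorm(50, 0), rnorm(50, 1.2)); y2 <- rep(0:1, each = 50)
  expect_equal(mutualInfoScore(exp(v2), y2), mutualInfoScore(v2, y2),
               tolerance = 0.1)
  expect_equal(mutualInfoScore(rep(3, 20), rep(0:1, 10)), 0)
})

test_that("-log10 transform handles landmarks and the p = 0 cap", {
  expect_equal(as.numeric(negLog10P(0.05)), 1.3010, tolerance = 1e-4)
  expect_equal(as.numeric(negLog10P(1)), 0)
  expect_equal(as.numeric(negLog10P(0.001)), 3)
  z <- negLog10P(0)
  expect_equal(as.numeric(z), 300)
  expect_true(attr(z, "capped"))
  expect_error(negLog10P(1.5), "must lie")
})

test_that("z-scoring standardises, is idempotent and affine-equivariant", {
  z <- zscoreValues(c(1, 2, 3))
  expect_equal(mean(z), 0); expect_equal(sd(z), 1)
  expect_equal(zscoreValues(z), z, tolerance = 1e-12)
  x <- rnorm(30)
  expect_equal(zscoreValues(3 * x + 7), zscoreValues(x), tolerance = 1e-12)
  expect_equal(zscoreValues(-2 * x), -zscoreValues(x), tolerance = 1e-12)
  zz <- zscoreValues(rep(4, 5))
  expect_equal(zz, rep(0, 5), ignore_attr = TRUE)
  expect_true(attr(zz, "degenerate"))
})

test_that("range-adjusted mean-difference ranking scales as documented", {
  tbl <- data.frame(dm_status = rep(c("DM", "non-DM"), each = 4),
                    f_equal = rep(1:4, 2),
                    f_narrow = c(2, 2, 2, 2, 1, 1, 1, 1),
                    f_wide = c(20, 20, 20, 20, 10, 10, 10, 10) / 1)
  tbl$f_wide <- c(20, 20, 20, 20.9, 10, 10, 10, 10.9) * 1  # range 10.9
  rk <- absMeanDiffRanking(tbl, features = c("f_equal", "f_narrow", "f_wide"))
  expect_equal(rk$score[rk$feature == "f_equal"], 0)
  # identical raw difference, ranges 1 vs 10 -> scores differ 10x
  tbl2 <- data.frame(dm_status = rep(c("DM", "non-DM"), each = 2),
                     a = c(1.5, 2.5, 1.0, 2.0),   # diff 0.5, range 1.5
                     b = c(15, 25, 10, 20) / 10 * c(10, 10, 10, 10))
  tbl2$b <- c(5.5, 15.5, 5.0, 15.0)               # diff 0.5, range 10.5
  rka <- absMeanDiffRanking(tbl2, features = c("a", "b"))
  expect_equal(rka$score[rka$feature == "a"] /
                 rka$score[rka$feature == "b"], 10.5 / 1.5, tolerance = 1e-9)
  # area exclusion
  tbl$area <- rnorm(8)
  expect_false("area" %in% absMeanDiffRanking(tbl, features = c("area", "f_wide"),
                                              excludeArea = TRUE)$feature)
})

test_that("feature screening gates on p < alpha and handles edge cases", {
  set.seed(10)
  tbl <- data.frame(dm_status = rep(c("DM", "non-DM"), each = 12),
                    strong = c(rnorm(12, 10), rnorm(12, 0)),
                    noise = rnorm(24),
                    flat = rep(1, 24))
  sc <- screenFeatures(tbl, alpha = 0.05,
                       features = c("strong", "noise", "flat"))
  expect_true(sc$retained[sc$feature == "strong"])
  expect_false(sc$retained[sc$feature == "flat"])
  expect_equal(sc$df, rep(22, 3))
  expect_true(all(sc$p_value >= 0 & sc$p_value <= 1))
  expect_true(all(sc$mi_score >= 0))
  # alpha = 0: strict inequality retains nothing
  sc0 <- screenFeatures(tbl, alpha = 0, features = c("strong", "noise"))
  expect_false(any(sc0$retained))
  one <- tbl[tbl$dm_status == "DM", ]
  expect_error(screenFeatures(one), "two levels|both classes")
})
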