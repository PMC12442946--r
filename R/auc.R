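# Univariate logistic discrimination: ROC/AUC in the feature's ascending
# orientation (no sign flipping, so AUC < 0.5 is possible) with stratified
# bootstrap percentile confidence intervals.

#' Tie-corrected Mann-Whitney AUC in ascending orientation
#'
#' `P(X_pos > X_neg) + 0.5 P(X_pos = X_neg)` via midranks, equivalent to
#' the trapezoidal area under the ROC curve with half-credit for ties.
#' Deliberately NOT flipped when below 0.5.
#'
#' @param values numeric predictor.
#' @param labels binary labels (positive = `"DM"`/1/TRUE).
#' @return AUC in \[0, 1\].
#' @export
aucFromValues <- function(values, labels) {
  y <- asBinaryLabel(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(values)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve (ascending orientation)
#'
#' @param values numeric predictor.
#' @param labels binary labels.
#' @return data.frame with `threshold`, `fpr`, `tpr`; thresholds sweep the
#'   observed values from high to low ("positive" when value > threshold).
#' @export
rocCurve <- function(values, labels) {
  y <- asBinaryLabel(labels)
  th <- c(Inf, sort(unique(values), decreasing = TRUE))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  fpr <- vapply(th, function(t) sum(values >= t & y == 0) / n0, 0)
  tpr <- vapply(th, function(t) sum(values >= t & y == 1) / n1, 0)
  data.frame(threshold = th, fpr = fpr, tpr = tpr)
}

#' Stratified bootstrap percentile confidence interval of a statistic
#'
#' Resamples with replacement within each class at the original class
#' sizes (preserving class proportions), recomputes the statistic and
#' reports the 2.5th/97.5th percentiles. Replicates where the statistic is
#' not defined (returns NA) are skipped and counted.
#'
#' @param values numeric vector.
#' @param labels binary labels.
#' @param statistic `function(values, labels)` returning a scalar.
#' @param nBoot number of resamples.
#' @param seed integer seed (fixed seed gives identical intervals).
#' @param probs percentile pair.
#' @return list with `ciLow`, `ciHigh`, `nBoot`, `nSkipped`, `replicates`.
#' @export
stratifiedBootstrapCi <- function(values, labels, statistic = aucFromValues,
                                  nBoot = 2000, seed = 1,
                                  probs = c(0.025, 0.975)) {
  y <- asBinaryLabel(labels)
  idx1 <- which(y == 1); idx0 <- which(y == 0)
  if (length(idx1) < 3 || length(idx0) < 3)
    stop("each class needs at least 3 members for the stratified bootstrap")
  reps <- withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      take <- c(sample(idx1, length(idx1), replace = TRUE),
                sample(idx0, length(idx0), replace = TRUE))
      statistic(values[take], y[take])
    }, 0)
  })
  ok <- is.finite(reps)
  q <- stats::quantile(reps[ok], probs, names = FALSE, type = 7)
  list(ciLow = q[1], ciHigh = q[2], nBoot = nBoot,
       nSkipped = sum(!ok), replicates = reps[ok])
}

#' Univariate logistic discrimination with bootstrap AUC interval
#'
#' Fits an unregularised single-predictor logistic regression on the
#' z-scored feature (coefficients reported; perfect separation flagged)
#' and evaluates discrimination by the tie-corrected Mann-Whitney AUC of
#' the feature in ascending orientation. Because the orientation is fixed
#' (never flipped to exceed 0.5), the AUC of the fitted monotone model
#' equals the AUC of the raw values, and each stratified bootstrap
#' replicate recomputes that AUC on the resample. The 95% interval is the
#' 2.5/97.5 percentile pair of the bootstrap distribution.
#'
#' @param values numeric feature (n >= 10).
#' @param labels binary labels (positive = `"DM"`/1/TRUE).
#' @param nBoot bootstrap resamples.
#' @param seed integer seed.
#' @return list of class `"AUCResult"`: `auc`, `ciLow`, `ciHigh`, `nBoot`,
#'   `nSkipped`, `seed`, `coef` (intercept/slope on the z scale),
#'   `separationFlag`, `degenerate`, `roc` (data.frame).
#' @export
univariateLogisticAuc <- function(values, labels, nBoot = 2000, seed = 1) {
  y <- asBinaryLabel(labels)
  if (length(values) < 10) stop("need at least 10 observations")
  if (length(unique(y)) < 2) stop("both classes must be present")
  z <- zscoreValues(values)
  degenerate <- isTRUE(attr(z, "degenerate"))
  # complete separation: one class entirely above the other
  sepFlag <- !degenerate &&
    (max(values[y == 0]) < min(values[y == 1]) ||
     max(values[y == 1]) < min(values[y == 0]))
  coefs <- c(NA_real_, NA_real_)
  if (!degenerate) {
    fit <- withCallingHandlers(
      stats::glm(y ~ z, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                  conditionMessage(w)))
          sepFlag <<- TRUE
        invokeRestart("muffleWarning")
      })
    coefs <- unname(stats::coef(fit))
  }
  auc <- aucFromValues(values, y)
  ci <- stratifiedBootstrapCi(values, y, statistic = aucFromValues,
                              nBoot = nBoot, seed = seed)
  structure(list(auc = auc, ciLow = ci$ciLow, ciHigh = ci$ciHigh,
                 nBoot = nBoot, nSkipped = ci$nSkipped, seed = seed,
                 coef = coefs, separationFlag = sepFlag,
                 degenerate = degenerate,
                 roc = rocCurve(values, y)),
            class = "AUCResult")
}

#' @export
print.AUCResult <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f, %d stratified resamples%s)\n",
              x$auc, x$ciLow, x$ciHigh, x$nBoot,
              if (x$separationFlag) ", separation flagged" else ""))
  invisible(x)
}

#' AUC screening across retained features
#'
#' Runs [univariateLogisticAuc()] for each feature, with per-feature seeds
#' derived from the master seed.
#'
#' @param featureTable data.frame with feature columns plus `dm_status`.
#' @param features feature columns; defaults to all canonical features
#'   present.
#' @param nBoot bootstrap resamples.
#' @param seed master seed.
#' @return data.frame: `feature`, `auc`, `ci_low`, `ci_high`, `n_boot`.
#' @export
aucTable <- function(featureTable, features = NULL, nBoot = 2000, seed = 1) {
  features <- features %||% intersect(featureNames(), names(featureTable))
  y <- asBinaryLabel(featureTable$dm_status)
  rows <- lapply(seq_along(features), function(i) {
    f <- features[i]
    r <- univariateLogisticAuc(featureTable[[f]], y, nBoot = nBoot,
                               seed = deriveSeed(seed, i))
    data.frame(feature = f, auc = r$auc, ci_low = r$ciLow, ci_high = r$ciHigh,
               n_boot = nBoot, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
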