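# Univariate biomarker screening: pooled t-test gate, Spearman correlation,
# -log10(p) ranking, k-nearest-neighbour mutual information, and
# range-adjusted absolute mean-difference ranking.

#' Pooled-variance two-sample Student t-test
#'
#' Classical equal-variance Student t with `df = n1 + n2 - 2` (the pooled
#' form, not Welch). Zero pooled variance is handled explicitly: equal
#' means give `t = 0, p = 1`; unequal means give an infinite t with
#' `p = 0` and an `infinite` flag.
#'
#' @param groupA,groupB numeric vectors (each length >= 2, finite).
#' @return list with `t`, `p`, `df`, `meanA`, `meanB`.
#' @examples
#' twoSampleTTest(rnorm(24), rnorm(24))$df  # 46
#' @export
twoSampleTTest <- function(groupA, groupB) {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("each group needs at least 2 observations")
  if (!all(is.finite(groupA)) || !all(is.finite(groupB)))
    stop("values must be finite")
  n1 <- length(groupA); n2 <- length(groupB)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(groupA) + (n2 - 1) * stats::var(groupB)) / df
  if (sp2 == 0) {
    if (mean(groupA) == mean(groupB))
      return(list(t = 0, p = 1, df = df, meanA = mean(groupA),
                  meanB = mean(groupB), infinite = FALSE))
    return(list(t = sign(mean(groupA) - mean(groupB)) * Inf, p = 0, df = df,
                meanA = mean(groupA), meanB = mean(groupB), infinite = TRUE))
  }
  tt <- stats::t.test(groupA, groupB, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       meanA = mean(groupA), meanB = mean(groupB), infinite = FALSE)
}

#' Spearman rank correlation against a binary label
#'
#' Midrank tie handling; two-sided p-value from the
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` approximation. Constant value
#' vectors return `rho = 0` with a degenerate flag.
#'
#' @param values numeric vector (n >= 4).
#' @param labels binary labels (0/1, logical, or a two-level factor where
#'   the "positive"/diseased class is the higher level).
#' @return list with `rho`, `p`, `degenerate`.
#' @export
spearmanVsLabel <- function(values, labels) {
  y <- as.numeric(asBinaryLabel(labels))
  n <- length(values)
  if (n < 4) stop("need at least 4 observations")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (stats::sd(values) == 0)
    return(list(rho = 0, p = 1, degenerate = TRUE))
  rho <- stats::cor(rank(values), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0, degenerate = FALSE))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2),
       degenerate = FALSE)
}

#' @noRd
asBinaryLabel <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    u <- sort(unique(labels))
    if (!all(u %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  ch <- as.character(labels)
  u <- sort(unique(ch))
  if (length(u) != 2) stop("labels must have exactly two levels")
  # 'DM' (diseased) is the positive class when present
  pos <- if ("DM" %in% u) "DM" else u[2]
  as.integer(ch == pos)
}

#' Mutual information between a continuous feature and a binary label
#'
#' k-nearest-neighbour estimator for the continuous-feature /
#' discrete-label case (Ross 2014): for each point, the distance to its
#' k-th neighbour within the same class defines a ball, and the number of
#' points of any class inside that ball enters a digamma average.
#' Negative estimates are clipped at 0; constant features return 0.
#'
#' @param values numeric vector (n >= 10).
#' @param labels binary labels (see [spearmanVsLabel()]).
#' @param k neighbour count.
#' @return mutual information in nats (>= 0).
#' @export
mutualInfoScore <- function(values, labels, k = 3) {
  y <- asBinaryLabel(labels)
  n <- length(values)
  if (n < 10) stop("need at least 10 observations")
  if (stats::sd(values) == 0) return(0)
  psiN <- digamma(n)
  psiK <- digamma(k)
  psiNc <- numeric(n)
  psiM <- numeric(n)
  ax <- abs(outer(values, values, "-"))
  for (i in seq_len(n)) {
    same <- which(y == y[i] & seq_len(n) != i)
    Nc <- length(same) + 1
    if (length(same) < k) { psiNc[i] <- NA; next }
    d <- sort(ax[i, same])[k]
    m <- sum(ax[i, -i] <= d)   # neighbours of any class within the ball
    psiNc[i] <- digamma(Nc)
    psiM[i] <- digamma(max(m, k))
  }
  ok <- !is.na(psiNc)
  mi <- psiN + psiK - mean(psiNc[ok]) - mean(psiM[ok])
  max(0, mi)
}

#' -log10 transform of a p-value
#'
#' @param p p-value in (0, 1\]; exact zeros are capped.
#' @param cap value returned for p = 0.
#' @return the ranking score `-log10(p)`.
#' @export
negLog10P <- function(p, cap = 300) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  out <- ifelse(p == 0, cap, -log10(p))
  attr(out, "capped") <- any(p == 0)
  out
}

#' Standardise values to zero mean and unit variance
#'
#' @param values numeric vector.
#' @return z-scored vector; a zero-variance input returns zeros with a
#'   `degenerate` attribute.
#' @export
zscoreValues <- function(values) {
  s <- stats::sd(values)
  if (is.na(s) || s == 0) {
    out <- rep(0, length(values))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (values - mean(values)) / s
}

#' Range-adjusted absolute mean-difference ranking
#'
#' Per feature, `|mean(DM) - mean(non-DM)|` divided by the observed range
#' of the feature over the whole table; features are partitioned by the
#' sign of the raw difference (which class has the higher mean). The area
#' feature can be excluded (it otherwise dominates the scale).
#'
#' @param featureTable data.frame with feature columns plus `dm_status`.
#' @param features columns to rank; defaults to all canonical features
#'   present.
#' @param excludeArea drop the `area` feature before ranking.
#' @return data.frame sorted by descending score, with columns `feature`,
#'   `mean_dm`, `mean_non_dm`, `raw_diff`, `score`, `higher_in`.
#' @export
absMeanDiffRanking <- function(featureTable, features = NULL,
                               excludeArea = FALSE) {
  y <- asBinaryLabel(featureTable$dm_status)
  if (length(unique(y)) < 2) stop("both classes must be present")
  features <- features %||% intersect(featureNames(), names(featureTable))
  if (excludeArea) features <- setdiff(features, "area")
  rows <- lapply(features, function(f) {
    v <- featureTable[[f]]
    mdm <- mean(v[y == 1]); mnd <- mean(v[y == 0])
    rng <- diff(range(v))
    score <- if (rng == 0) 0 else abs(mdm - mnd) / rng
    data.frame(feature = f, mean_dm = mdm, mean_non_dm = mnd,
               raw_diff = mdm - mnd, score = score,
               higher_in = if (mdm >= mnd) "DM" else "non-DM",
               zero_range = rng == 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$score), , drop = FALSE]
}

#' Screen features as candidate diabetes-status biomarkers
#'
#' For every feature column: pooled two-sample t-test between classes
#' (retention gate `p < alpha`, strict), Spearman rank correlation with
#' the label, `-log10(p)`, k-NN mutual information and the range-adjusted
#' absolute mean difference.
#'
#' @param featureTable data.frame with feature columns plus a `dm_status`
#'   column (two classes, each with >= 2 rows).
#' @param alpha retention threshold for the t-test gate.
#' @param features columns to screen; defaults to all canonical features
#'   present.
#' @param miK neighbour count for the mutual-information estimator.
#' @return data.frame (one row per feature): `feature`, `t_value`,
#'   `p_value`, `df`, `mean_dm`, `mean_non_dm`, `abs_mean_diff_adj`,
#'   `spearman_rho`, `spearman_p`, `neglog10_p`, `mi_score`, `retained`.
#' @export
screenFeatures <- function(featureTable, alpha = 0.05, features = NULL,
                           miK = 3) {
  if (!"dm_status" %in% names(featureTable)) stop("dm_status column required")
  y <- asBinaryLabel(featureTable$dm_status)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (min(table(y)) < 2) stop("each class needs at least 2 rows")
  features <- features %||% intersect(featureNames(), names(featureTable))
  adj <- absMeanDiffRanking(featureTable, features)
  rows <- lapply(features, function(f) {
    v <- featureTable[[f]]
    constant <- stats::sd(v) == 0
    tt <- if (constant)
      list(t = 0, p = 1, df = length(v) - 2,
           meanA = mean(v[y == 1]), meanB = mean(v[y == 0]))
    else twoSampleTTest(v[y == 1], v[y == 0])
    sp <- spearmanVsLabel(v, y)
    mi <- if (constant) 0 else mutualInfoScore(v, y, k = miK)
    data.frame(feature = f,
               t_value = tt$t, p_value = tt$p, df = tt$df,
               mean_dm = tt$meanA, mean_non_dm = tt$meanB,
               abs_mean_diff_adj = adj$score[match(f, adj$feature)],
               spearman_rho = sp$rho, spearman_p = sp$p,
               neglog10_p = as.numeric(negLog10P(tt$p)),
               mi_score = mi,
               retained = is.finite(tt$p) && tt$p < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
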