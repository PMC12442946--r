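# CEM43 thermal dosimetry, safety verdicts and field comparison.

#' Sapareto-Dewey CEM43 thermal dose of a thermal field
#'
#' `CEM43 = sum R^(43 - T) * dt` (minutes) accumulated over the stored
#' snapshots (piecewise-constant in each inter-frame interval), with
#' `R = 0.5` for `T >= 43 C` and `R = 0.25` below. Monotone nondecreasing
#' in time by construction.
#'
#' @param field a [ThermalField-class].
#' @return a [DoseMap-class].
#' @export
thermalDose <- function(field) {
  tms <- field@frameTimes
  nf <- length(tms)
  if (nf < 2) stop("need at least two frames to accumulate dose")
  cem <- matrix(0, dim(field@frames)[1], dim(field@frames)[2])
  for (i in seq_len(nf - 1)) {
    Tm <- field@frames[, , i]
    dtMin <- (tms[i + 1] - tms[i]) / 60
    R <- ifelse(Tm >= 43, 0.5, 0.25)
    cem <- cem + R^(43 - Tm) * dtMin
  }
  methods::new("DoseMap", cem = cem, r = field@r, z = field@z,
               tissueIndex = field@tissueIndex, layerNames = field@layerNames)
}

#' Safety report for a sonication
#'
#' Per-tissue maximum temperature and CEM43, compared against the
#' configured thresholds: maximum CEM43 below `cemLimit` (default 240
#' equivalent minutes, the conventional tissue-damage bound) and
#' pancreatic peak temperature below `pancTLimit` (default 40 C, the
#' stimulation-safety bound). Duty factors at or above `dutyAvoid`
#' (default 75%) carry an advisory avoid flag.
#'
#' @param dose a [DoseMap-class].
#' @param field the matching [ThermalField-class].
#' @param stack the [TissueStack-class] that was simulated.
#' @param protocol the [SonicationProtocol-class] (for the duty flag);
#'   optional.
#' @param cemLimit,pancTLimit,dutyAvoid thresholds.
#' @return list with `perTissue` (data.frame: tissue, max_T, max_cem43),
#'   `pass` (overall verdict), `cemPass`, `pancTempPass`, `dutyFlag`.
#' @export
safetyReport <- function(dose, field, stack, protocol = NULL,
                         cemLimit = 240, pancTLimit = 40, dutyAvoid = 0.75) {
  L <- layers(stack)
  per <- do.call(rbind, lapply(seq_len(nrow(L)), function(i) {
    cols <- which(field@tissueIndex == i)
    data.frame(tissue = L$name[i],
               max_T = if (length(cols)) max(field@maxT[, cols]) else NA_real_,
               max_cem43 = if (length(cols)) max(dose@cem[, cols]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  cemPass <- max(per$max_cem43, na.rm = TRUE) < cemLimit
  pT <- per$max_T[per$tissue == "pancreas"]
  pancPass <- if (length(pT) && is.finite(pT)) pT < pancTLimit else NA
  dutyFlag <- !is.null(protocol) && protocol@dutyFactor >= dutyAvoid
  list(perTissue = per, pass = isTRUE(cemPass) && isTRUE(pancPass),
       cemPass = cemPass, pancTempPass = pancPass, dutyFlag = dutyFlag,
       cemLimit = cemLimit, pancTLimit = pancTLimit)
}

#' RMSE between the on-axis temperature series of two thermal fields
#'
#' Both fields are linearly interpolated in time onto the overlapping
#' time range (sampled at the coarser field's snapshots) and in depth
#' onto the coarser z grid; the root-mean-square temperature difference
#' over all (z, t) samples is returned, in degrees C.
#'
#' @param a,b [ThermalField-class] objects over comparable geometry.
#' @return RMSE in degrees C.
#' @export
rmseBetweenFields <- function(a, b) {
  t0 <- max(min(a@onAxisTimes), min(b@onAxisTimes))
  t1 <- min(max(a@onAxisTimes), max(b@onAxisTimes))
  if (t1 <= t0) stop("fields have no overlapping time range")
  # evaluate on the coarser of the two samplings
  ref <- if (length(a@z) <= length(b@z)) a else b
  oth <- if (length(a@z) <= length(b@z)) b else a
  keep <- which(ref@onAxisTimes >= t0 & ref@onAxisTimes <= t1)
  if (length(keep) > 400) keep <- keep[round(seq(1, length(keep), length.out = 400))]
  zz <- ref@z
  sqsum <- 0; n <- 0
  othT <- oth@onAxisTimes
  for (k in keep) {
    tk <- ref@onAxisTimes[k]
    va <- ref@onAxis[, k]
    j <- min(max(findInterval(tk, othT), 1L), length(othT) - 1L)
    w <- (tk - othT[j]) / (othT[j + 1] - othT[j])
    w <- min(max(w, 0), 1)
    vb <- (1 - w) * oth@onAxis[, j] + w * oth@onAxis[, j + 1]
    vbOnRef <- stats::approx(oth@z, vb, zz, rule = 2)$y
    sqsum <- sqsum + sum((va - vbOnRef)^2)
    n <- n + length(zz)
  }
  sqrt(sqsum / n)
}
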