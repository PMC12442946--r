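# Gray-level co-occurrence matrix and the 13 Haralick texture statistics.
#
# Conventions (fixed and documented because Haralick values differ between
# implementations): in-mask intensities are min-max quantised to `levels`
# bins; pixel pairs are counted only when BOTH endpoints are in-mask;
# counts are accumulated over all requested angles at the given distance,
# then symmetrised by adding the transpose and normalised to sum 1.
# Entropies use log base 2 with 0 log 0 := 0.

#' Compute a masked gray-level co-occurrence matrix
#'
#' @param image an [UltrasoundImage-class] or numeric matrix.
#' @param mask a [PancreasMask-class] or logical matrix of the same shape.
#' @param levels number of quantisation levels.
#' @param distance pixel offset distance.
#' @param angles offset directions in degrees, subset of 0/45/90/135.
#' @return list of class `"GLCM"` with elements `matrix` (levels x levels,
#'   symmetric, sums to 1), `levels`, `distance`, `angles`, `nPairs`,
#'   `degenerate` (TRUE when fewer than two distinct in-mask gray levels
#'   survive quantisation).
#' @export
computeGLCM <- function(image, mask, levels = 32, distance = 1,
                        angles = c(0, 45, 90, 135)) {
  px <- if (is(image, "UltrasoundImage")) pixels(image) else image
  m <- if (is(mask, "PancreasMask")) maskMatrix(mask) else mask
  if (!all(dim(px) == dim(m))) stop("image and mask shapes differ")
  if (!any(m)) stop("empty mask")
  if (!all(angles %in% c(0, 45, 90, 135))) stop("angles must be in {0,45,90,135}")
  v <- px[m]
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    return(structure(list(matrix = matrix(1, 1, 1), levels = 1L,
                          distance = distance, angles = angles,
                          nPairs = 0L, degenerate = TRUE), class = "GLCM"))
  }
  L <- as.integer(levels)
  q <- matrix(NA_integer_, nrow(px), ncol(px))
  q[m] <- pmin(L, floor((v - lo) / (hi - lo) * L) + 1L)

  d <- as.integer(distance)
  offs <- list(`0` = c(0, d), `45` = c(-d, d), `90` = c(-d, 0), `135` = c(-d, -d))
  counts <- numeric(L * L)
  nr <- nrow(q); nc <- ncol(q)
  nPairs <- 0L
  for (a in as.character(angles)) {
    o <- offs[[a]]
    r1 <- max(1, 1 - o[1]):min(nr, nr - o[1])
    c1 <- max(1, 1 - o[2]):min(nc, nc - o[2])
    A <- q[r1, c1, drop = FALSE]
    B <- q[r1 + o[1], c1 + o[2], drop = FALSE]
    ok <- !is.na(A) & !is.na(B)
    if (!any(ok)) next
    k <- (A[ok] - 1L) * L + B[ok]
    counts <- counts + tabulate(k, L * L)
    nPairs <- nPairs + sum(ok)
  }
  if (nPairs < 2) stop("degenerate GLCM input: fewer than 2 valid in-mask pairs")
  C <- matrix(counts, L, L, byrow = TRUE)  # row index i, col index j
  C <- C + t(C)
  structure(list(matrix = C / sum(C), levels = L, distance = distance,
                 angles = angles, nPairs = nPairs, degenerate = FALSE),
            class = "GLCM")
}

#' The 13 Haralick features of a normalised GLCM
#'
#' Standard definitions: angular second moment, contrast, correlation,
#' variance (sum of squares), inverse difference moment, sum average /
#' variance / entropy over the `i + j` marginal, entropy, difference
#' entropy over the `|i - j|` marginal, and the two information measures of
#' correlation. Entropies are in bits; IMC2 uses the conventional
#' `sqrt(1 - exp(-2 (HXY2 - HXY)))` form. A degenerate (single-level) GLCM
#' yields the documented limit values (ASM = IDM = correlation = 1,
#' entropies and contrast 0) with a `degenerate` attribute.
#'
#' @param glcm result of [computeGLCM()].
#' @return named numeric vector of the 13 features, prefixed `haralick_`.
#' @export
haralickFeatures <- function(glcm) {
  stopifnot(inherits(glcm, "GLCM"))
  P <- glcm$matrix
  if (glcm$degenerate || glcm$levels == 1) {
    out <- c(asm = 1, contrast = 0, correlation = 1, variance = 0, idm = 1,
             sum_average = 2, sum_variance = 0, sum_entropy = 0, entropy = 0,
             difference_variance = 0, difference_entropy = 0, imc1 = 0, imc2 = 0)
    names(out) <- paste0("haralick_", names(out))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  if (abs(sum(P) - 1) > 1e-9) stop("GLCM must be normalised (sum 1)")
  L <- glcm$levels
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(L) * px); muy <- sum(seq_len(L) * py)
  sx <- sqrt(sum((seq_len(L) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(L) - muy)^2 * py))
  asm <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  correlation <- if (sx * sy == 0) 1 else (sum(i * j * P) - mux * muy) / (sx * sy)
  variance <- sum((i - mux)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))
  # i + j marginal (k = 2 .. 2L)
  psum <- as.numeric(tapply(P, i + j, sum))
  ksum <- sort(unique(as.vector(i + j)))
  sumAvg <- sum(ksum * psum)
  sumVar <- sum((ksum - sumAvg)^2 * psum)
  sumEnt <- entropyBits(psum)
  ent <- entropyBits(as.vector(P))
  pdiff <- as.numeric(tapply(P, abs(i - j), sum))
  kdiff <- sort(unique(as.vector(abs(i - j))))
  diffMean <- sum(kdiff * pdiff)
  diffVar <- sum((kdiff - diffMean)^2 * pdiff)
  diffEnt <- entropyBits(pdiff)
  hx <- entropyBits(px); hy <- entropyBits(py)
  pp <- outer(px, py)
  lg <- ifelse(pp > 0, log2(pp), 0)
  hxy1 <- -sum(P * lg)
  hxy2 <- -sum(pp * lg)
  imc1 <- if (max(hx, hy) == 0) 0 else (ent - hxy1) / max(hx, hy)
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - ent))))
  out <- c(asm = asm, contrast = contrast, correlation = correlation,
           variance = variance, idm = idm, sum_average = sumAvg,
           sum_variance = sumVar, sum_entropy = sumEnt, entropy = ent,
           difference_variance = diffVar, difference_entropy = diffEnt,
           imc1 = imc1, imc2 = imc2)
  names(out) <- paste0("haralick_", names(out))
  attr(out, "degenerate") <- FALSE
  out
}
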