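# Intensity entropy, local binary patterns and Sobel gradient magnitude.

#' Shannon entropy of the in-mask intensity histogram
#'
#' 256 integer bins (0-255), base-2 logarithm, `0 log 0 := 0`.
#'
#' @param image an [UltrasoundImage-class] or numeric matrix (0-255).
#' @param mask a [PancreasMask-class] or logical matrix.
#' @return entropy in bits (0 for a constant region; 8 is the maximum).
#' @export
intensityEntropy <- function(image, mask) {
  px <- if (is(image, "UltrasoundImage")) pixels(image) else image
  m <- if (is(mask, "PancreasMask")) maskMatrix(mask) else mask
  if (!any(m)) stop("empty mask")
  v <- round(px[m])
  entropyBits(tabulate(v + 1L, 256L) / length(v))
}

#' Rotation-invariant uniform local binary patterns
#'
#' Circular sampling of `points` neighbours at radius `radius` (bilinear
#' interpolation off-grid), thresholded against the centre. Uniform codes
#' (at most two 0/1 transitions around the circle) map to the number of
#' set bits; non-uniform codes share one bin, giving `points + 2` bins.
#' Only pixels whose full square neighbourhood (side `2 ceil(radius) + 1`)
#' lies inside the mask contribute.
#'
#' @param image image or matrix (0-255).
#' @param mask mask or logical matrix.
#' @param radius sampling radius, pixels.
#' @param points number of circle samples.
#' @return list with `histogram` (probabilities over the
#'   `points + 2` bins), `energy` (sum of squared probabilities) and
#'   `entropy` (bits).
#' @export
lbpFeatures <- function(image, mask, radius = 1, points = 8) {
  px <- if (is(image, "UltrasoundImage")) pixels(image) else image
  m <- if (is(mask, "PancreasMask")) maskMatrix(mask) else mask
  if (!all(dim(px) == dim(m))) stop("image and mask shapes differ")
  nr <- nrow(px); nc <- ncol(px)
  R <- as.integer(ceiling(radius))
  # centres whose full (2R+1)^2 neighbourhood is in-mask and in-bounds
  ok <- m
  for (dr in -R:R) for (dc in -R:R) {
    sh <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 - dc):min(nc, nc - dc)
    sh[rs, cs] <- m[rs + dr, cs + dc]
    ok <- ok & sh
  }
  centres <- which(ok)
  if (!length(centres)) stop("degenerate LBP input: eroded mask is empty")
  cr <- ((centres - 1) %% nr) + 1
  cc <- ((centres - 1) %/% nr) + 1
  gc <- px[centres]
  P <- as.integer(points)
  S <- matrix(FALSE, length(centres), P)
  for (p in seq_len(P) - 1L) {
    a <- 2 * pi * p / P
    dr <- -radius * sin(a); dc <- radius * cos(a)
    rr <- cr + dr; ccn <- cc + dc
    r0 <- pmin(floor(rr), nr - 1); c0 <- pmin(floor(ccn), nc - 1)
    fr <- rr - r0; fc <- ccn - c0
    # bilinear interpolation (neighbourhood containment guarantees bounds)
    g <- px[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
         px[cbind(r0 + 1, c0)] * fr * (1 - fc) +
         px[cbind(r0, c0 + 1)] * (1 - fr) * fc +
         px[cbind(r0 + 1, c0 + 1)] * fr * fc
    # tolerance absorbs bilinear round-off so exact ties compare equal
    S[, p + 1L] <- g >= gc - 1e-7
  }
  trans <- rowSums(S != S[, c(2:P, 1), drop = FALSE])
  nset <- rowSums(S)
  code <- ifelse(trans <= 2, nset, P + 1L)   # bins 0..P+1
  h <- tabulate(code + 1L, P + 2L)
  prob <- h / sum(h)
  list(histogram = prob, energy = sum(prob^2), entropy = entropyBits(prob))
}

#' Mean Sobel gradient magnitude over the mask interior
#'
#' 3x3 Sobel kernels normalised so that a unit-slope intensity ramp yields
#' magnitude 1 gray/px; averaged over pixels whose full 3x3 neighbourhood
#' is in-mask.
#'
#' @param image image or matrix (0-255).
#' @param mask mask or logical matrix.
#' @return mean gradient magnitude, gray levels per pixel.
#' @export
gradientMagnitude <- function(image, mask) {
  px <- if (is(image, "UltrasoundImage")) pixels(image) else image
  m <- if (is(mask, "PancreasMask")) maskMatrix(mask) else mask
  if (!any(m)) stop("empty mask")
  nr <- nrow(px); nc <- ncol(px)
  if (nr < 3 || nc < 3) stop("image too small for Sobel gradients")
  shift <- function(M, dr, dc) {
    out <- matrix(NA_real_, nr, nc)
    rs <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 - dc):min(nc, nc - dc)
    out[rs, cs] <- M[rs + dr, cs + dc]
    out
  }
  gx <- (shift(px, -1, 1) + 2 * shift(px, 0, 1) + shift(px, 1, 1) -
         shift(px, -1, -1) - 2 * shift(px, 0, -1) - shift(px, 1, -1)) / 8
  gy <- (shift(px, 1, -1) + 2 * shift(px, 1, 0) + shift(px, 1, 1) -
         shift(px, -1, -1) - 2 * shift(px, -1, 0) - shift(px, -1, 1)) / 8
  okm <- m
  for (dr in -1:1) for (dc in -1:1) okm <- okm & shift(m, dr, dc) %in% TRUE
  ok <- okm & !is.na(gx) & !is.na(gy)
  if (!any(ok)) return(0)
  mean(sqrt(gx[ok]^2 + gy[ok]^2))
}
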