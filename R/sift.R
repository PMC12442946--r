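# Scale-space keypoint counting: a compact difference-of-Gaussians detector
# (scale-space extrema with contrast and edge-curvature tests) whose only
# output used downstream is the number of keypoints inside the mask.

#' @noRd
downsample2 <- function(M) M[seq(1, nrow(M), 2), seq(1, ncol(M), 2), drop = FALSE]

#' Count scale-space difference-of-Gaussians keypoints inside a mask
#'
#' Builds a Gaussian scale-space pyramid (base sigma 1.6, 3 intervals per
#' octave), forms difference-of-Gaussians images and detects local extrema
#' over the 3x3x3 scale-space neighbourhood. Candidates must exceed the
#' contrast threshold (on unit-scaled intensities) and pass the standard
#' principal-curvature-ratio edge test; surviving keypoints are mapped
#' back to full-resolution coordinates and counted when they fall inside
#' the mask. Deterministic; no subpixel refinement.
#'
#' @param image image or matrix (0-255).
#' @param mask mask or logical matrix.
#' @param contrastThreshold minimum absolute DoG response (unit intensity
#'   scale).
#' @param edgeRatio maximum principal curvature ratio.
#' @param octaves number of octaves; by default as many as the geometry
#'   allows (down to 16 px).
#' @return integer keypoint count. Regions with a bounding box smaller
#'   than 16 x 16 px return 0 with attribute `degenerate = TRUE`.
#' @export
siftKeypointCount <- function(image, mask, contrastThreshold = 0.03,
                              edgeRatio = 10, octaves = NULL) {
  px <- if (is(image, "UltrasoundImage")) pixels(image) else image
  m <- if (is(mask, "PancreasMask")) maskMatrix(mask) else mask
  if (!all(dim(px) == dim(m))) stop("image and mask shapes differ")
  if (!any(m)) stop("empty mask")
  rows <- range(row(m)[m]); cols <- range(col(m)[m])
  if (diff(rows) + 1 < 16 || diff(cols) + 1 < 16) {
    out <- 0L; attr(out, "degenerate") <- TRUE
    return(out)
  }
  img <- px / 255
  nOct <- octaves %||% max(1L, floor(log2(min(dim(img)) / 16)))
  s <- 3L  # intervals per octave
  sigma0 <- 1.6
  count <- 0L
  base <- img
  maskOct <- m
  for (o in seq_len(nOct)) {
    sig <- sigma0 * 2^((0:(s + 2)) / s)
    G <- vector("list", s + 3)
    G[[1]] <- sepBlur(base, sig[1])
    for (i in 2:(s + 3)) {
      dsig <- sqrt(sig[i]^2 - sig[i - 1]^2)
      G[[i]] <- sepBlur(G[[i - 1]], dsig)
    }
    D <- lapply(1:(s + 2), function(i) G[[i + 1]] - G[[i]])
    nr <- nrow(base); nc <- ncol(base)
    if (nr >= 3 && nc >= 3) {
      ir <- 2:(nr - 1); ic <- 2:(nc - 1)
      for (l in 2:(s + 1)) {
        Dc <- D[[l]]
        centre <- Dc[ir, ic]
        isMax <- abs(centre) > contrastThreshold
        isMin <- isMax
        for (dl in -1:1) for (dr in -1:1) for (dc in -1:1) {
          if (dl == 0 && dr == 0 && dc == 0) next
          nb <- D[[l + dl]][ir + dr, ic + dc]
          isMax <- isMax & (centre > nb)
          isMin <- isMin & (centre < nb)
          if (!any(isMax) && !any(isMin)) break
        }
        cand <- which(isMax | isMin, arr.ind = TRUE)
        if (!nrow(cand)) next
        rr <- cand[, 1] + 1L; cc <- cand[, 2] + 1L
        # edge test from the spatial Hessian of the DoG
        dxx <- Dc[cbind(rr, cc + 1)] + Dc[cbind(rr, cc - 1)] - 2 * Dc[cbind(rr, cc)]
        dyy <- Dc[cbind(rr + 1, cc)] + Dc[cbind(rr - 1, cc)] - 2 * Dc[cbind(rr, cc)]
        dxy <- (Dc[cbind(rr + 1, cc + 1)] + Dc[cbind(rr - 1, cc - 1)] -
                Dc[cbind(rr + 1, cc - 1)] - Dc[cbind(rr - 1, cc + 1)]) / 4
        tr <- dxx + dyy
        det <- dxx * dyy - dxy^2
        keep <- det > 0 & (tr^2 / det) < ((edgeRatio + 1)^2 / edgeRatio)
        if (!any(keep)) next
        inMask <- maskOct[cbind(rr[keep], cc[keep])]
        count <- count + sum(inMask)
      }
    }
    if (o < nOct) {
      base <- downsample2(G[[s + 1]])
      maskOct <- downsample2(maskOct)
      if (min(dim(base)) < 16) break
    }
  }
  as.integer(count)
}
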