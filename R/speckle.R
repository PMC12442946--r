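# Speckle phantom primitive: smoothed complex circular-Gaussian field,
# envelope-detected and log-compressed.

#' Raw speckle envelope (pre log compression)
#'
#' The envelope is the magnitude of a complex field whose real and imaginary
#' parts are independent Gaussian white-noise images, each smoothed with a
#' Gaussian kernel of standard deviation `correlationLength` pixels. With
#' `correlationLength = 0` the per-pixel envelope is exactly Rayleigh
#' distributed; smoothing lengthens the spatial correlation of the speckle
#' while preserving the Rayleigh single-pixel statistics.
#'
#' A nonzero `coherent` amplitude adds a deterministic (specular)
#' in-phase component of `coherent` standard deviations of the diffuse
#' field, turning the envelope Rician: the relative amplitude spread
#' shrinks as the coherent fraction grows, which is how increased tissue
#' homogeneity (for example fibrotic or fatty replacement) lowers
#' first-order intensity entropy in the phantoms.
#'
#' @param shape integer length-2, rows x cols (each >= 8).
#' @param correlationLength nonnegative smoothing scale in pixels.
#' @param seed integer RNG seed; identical inputs give bit-identical output.
#' @param coherent nonnegative coherent-to-diffuse amplitude ratio
#'   (0 = fully developed Rayleigh speckle).
#' @return numeric matrix of nonnegative envelope values.
#' @export
speckleEnvelope <- function(shape, correlationLength = 0, seed = 1,
                            coherent = 0) {
  shape <- as.integer(shape)
  if (length(shape) != 2 || any(!is.finite(shape)) || any(shape < 8))
    stop("shape must be two integers, each >= 8")
  if (!is.finite(correlationLength) || correlationLength < 0)
    stop("correlationLength must be >= 0")
  if (!is.finite(coherent) || coherent < 0) stop("coherent must be >= 0")
  withSeed(seed, {
    re <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
    im <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
    if (correlationLength > 0) {
      re <- sepBlur(re, correlationLength)
      im <- sepBlur(im, correlationLength)
    }
    cc <- coherent * stats::sd(as.vector(re))
    sqrt((re + cc)^2 + im^2)
  })
}

#' Log compression of an envelope image
#'
#' `log(1 + beta * env / mean(env))`; the envelope is normalised to unit
#' mean first so the compression operating point does not depend on the
#' smoothing-induced variance loss.
#' @noRd
logCompress <- function(env, beta = 5) {
  log1p(beta * env / mean(env))
}

#' Generate a B-mode-like speckle image
#'
#' Envelope-detected speckle ([speckleEnvelope()]), log-compressed and
#' min-max quantised to the 8-bit range.
#'
#' @inheritParams speckleEnvelope
#' @param beta log-compression gain.
#' @return integer-valued matrix in \[0, 255\].
#' @examples
#' img <- generateSpeckle(c(64, 64), correlationLength = 1.5, seed = 7)
#' range(img)
#' @export
generateSpeckle <- function(shape, correlationLength = 0, seed = 1, beta = 5,
                            coherent = 0) {
  env <- speckleEnvelope(shape, correlationLength, seed, coherent)
  g <- logCompress(env, beta)
  rng <- range(g)
  if (diff(rng) == 0) return(matrix(0, nrow(g), ncol(g)))
  round(255 * (g - rng[1]) / diff(rng))
}
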