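# Internal helpers: seeded evaluation, seed derivation, separable blur.

#' Evaluate an expression under a fixed RNG seed without disturbing the
#' caller's random-number stream.
#' @noRd
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed and integer indices.
#'
#' Linear-congruential mixing, kept strictly below 2^31 so the result is a
#' valid R integer seed. Identical inputs give identical child seeds, so
#' per-image generation is reproducible (and order-independent).
#' @param master integer master seed.
#' @param ... integer indices (patient index, image index, ...).
#' @return a single integer in `[0, 2^31 - 1)`.
#' @export
deriveSeed <- function(master, ...) {
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (x in c(...)) {
    h <- (h * 48271 + (as.numeric(x) + 1) * 30269 + 1013904223) %% m
  }
  as.integer(h)
}

#' Truncated-and-renormalised Gaussian weight matrix for one dimension.
#' Row i holds the kernel centred on i; rows sum to one (replicate-style
#' edge handling).
#' @noRd
gaussBand <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  idx <- seq_len(n)
  W <- outer(idx, idx, function(i, j) {
    d <- i - j
    ifelse(abs(d) <= r, exp(-d^2 / (2 * sigma^2)), 0)
  })
  W / rowSums(W)
}

#' Separable Gaussian blur of a matrix (replicate edges).
#' @noRd
sepBlur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  Gr <- gaussBand(nrow(mat), sigma)
  Gc <- gaussBand(ncol(mat), sigma)
  Gr %*% mat %*% t(Gc)
}

#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shannon entropy (base 2) of a probability vector; 0 log 0 := 0.
#' @noRd
entropyBits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}
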