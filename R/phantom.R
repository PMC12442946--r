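# Class-labelled pancreas phantoms and synthetic cohorts.
#
# A phantom is a background speckle scene with a smooth, simply-connected
# pancreas-shaped blob (perturbed ellipse) whose inside-blob speckle uses a
# class-dependent correlation length. The diabetic class is encoded as
# smoother in-region texture, smaller area, shallower centroid and higher
# aspect ratio; all effect sizes are configurable through the spec objects.

#' Phantom specification
#'
#' Defaults encode the study conditions assumed throughout the package:
#' 160x160 pixels at 0.5 mm/px (an 8 x 8 cm field of view), a pancreas
#' cross-section of about 13 cm^2 centred 4.5 cm below the dermis for the
#' non-diabetic class, and for the diabetic class a 1.5x speckle correlation
#' length inside the region, a 0.8x area multiplier, a 0.5 cm shallower
#' centroid and a higher width-to-height aspect ratio. Within-class spreads
#' are package defaults, not literature values.
#'
#' @param classLabel `"DM"` or `"non-DM"`.
#' @param imageShape rows x cols, each >= 64.
#' @param pixelSpacing mm per pixel (> 0).
#' @param areaMean,areaSd region area, mm^2.
#' @param depthMean,depthSd centroid depth, cm from the dermis (row 1).
#' @param aspectMean,aspectSd width-to-height ratio of the generating ellipse.
#' @param textureSmoothing multiplier (>= 0) on the base in-region speckle
#'   correlation length (`baseCorrelation` pixels).
#' @param coherentAmplitude coherent-to-diffuse amplitude ratio of the
#'   in-region speckle ([speckleEnvelope()]); the diabetic default (2.5)
#'   narrows the amplitude distribution, lowering first-order and GLCM
#'   entropies as fibro-fatty homogenisation would.
#' @param baseCorrelation base in-region speckle correlation length, pixels.
#' @param backgroundCorrelation background speckle correlation length, pixels.
#' @param echogenicityOffset gray-level shift added inside the region after
#'   8-bit quantisation.
#' @param boundaryWobble relative amplitude of the low-order Fourier boundary
#'   perturbation (keeps the blob simply connected when small).
#' @param seed integer seed.
#' @return a list of class `"PhantomSpec"`.
#' @export
phantomSpec <- function(classLabel = c("non-DM", "DM"),
                        imageShape = c(160, 160),
                        pixelSpacing = 0.5,
                        areaMean = if (classLabel == "DM") 0.8 * 1300 else 1300,
                        areaSd = 160,
                        depthMean = if (classLabel == "DM") 4.0 else 4.5,
                        depthSd = 0.45,
                        aspectMean = if (classLabel == "DM") 1.9 else 1.6,
                        aspectSd = 0.2,
                        textureSmoothing = if (classLabel == "DM") 1.5 else 1.0,
                        coherentAmplitude = if (classLabel == "DM") 2.5 else 0,
                        baseCorrelation = 1.2,
                        backgroundCorrelation = 1.0,
                        echogenicityOffset = 15,
                        boundaryWobble = 0.06,
                        seed = 1) {
  classLabel <- match.arg(classLabel)
  imageShape <- as.integer(imageShape)
  if (length(imageShape) != 2 || any(imageShape < 64))
    stop("imageShape must be two integers >= 64")
  if (pixelSpacing <= 0) stop("pixelSpacing must be > 0")
  if (textureSmoothing < 0) stop("textureSmoothing must be >= 0")
  if (areaMean <= 0 || areaSd < 0) stop("invalid area parameters")
  structure(list(classLabel = classLabel, imageShape = imageShape,
                 pixelSpacing = pixelSpacing,
                 areaMean = areaMean, areaSd = areaSd,
                 depthMean = depthMean, depthSd = depthSd,
                 aspectMean = aspectMean, aspectSd = aspectSd,
                 textureSmoothing = textureSmoothing,
                 coherentAmplitude = coherentAmplitude,
                 baseCorrelation = baseCorrelation,
                 backgroundCorrelation = backgroundCorrelation,
                 echogenicityOffset = echogenicityOffset,
                 boundaryWobble = boundaryWobble,
                 seed = as.integer(seed)),
            class = "PhantomSpec")
}

#' Closed blob boundary: ellipse with low-order Fourier perturbation
#'
#' Returns an n-vertex polygon (x, y in 0-based pixel coordinates).
#' @noRd
blobBoundary <- function(centerX, centerY, semiX, semiY, wobble, n = 180) {
  theta <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  pert <- rep(1, n)
  for (k in 2:4) {
    eps <- stats::rnorm(1, 0, wobble)
    phi <- stats::runif(1, 0, 2 * pi)
    pert <- pert + eps * cos(k * theta + phi)
  }
  pert <- pmax(pert, 0.5)
  cbind(x = centerX + semiX * pert * cos(theta),
        y = centerY + semiY * pert * sin(theta))
}

#' Generate one pancreas phantom
#'
#' Samples region geometry (area, aspect, centroid depth) from the spec,
#' builds a perturbed-ellipse mask, and composes the scene in the envelope
#' domain: background speckle outside, class-smoothed speckle inside, then
#' joint log compression, 8-bit quantisation and an in-region echogenicity
#' shift. If the sampled blob exceeds the image bounds it is shrunk by 10%
#' and retried, up to 10 attempts.
#'
#' @param spec a [phantomSpec()].
#' @return list with elements `image` ([UltrasoundImage-class]),
#'   `mask` ([PancreasMask-class]) and `classLabel`.
#' @examples
#' ph <- generatePhantom(phantomSpec("DM", seed = 11))
#' ph$image
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  nr <- spec$imageShape[1]; nc <- spec$imageShape[2]
  sp <- spec$pixelSpacing

  geomSeed <- deriveSeed(spec$seed, 1L)
  texSeed <- deriveSeed(spec$seed, 2L)

  mask <- withSeed(geomSeed, {
    area <- max(spec$areaMean / 4, stats::rnorm(1, spec$areaMean, spec$areaSd))
    aspect <- max(1.05, stats::rnorm(1, spec$aspectMean, spec$aspectSd))
    depth <- stats::rnorm(1, spec$depthMean, spec$depthSd)
    depth <- clamp(depth, 0.15 * nr * sp / 10, 0.85 * nr * sp / 10)
    cy <- depth * 10 / sp                      # rows, 0-based
    cx <- nc / 2 + stats::rnorm(1, 0, nc / 20) # cols, 0-based
    areaPx <- area / sp^2
    m <- NULL
    for (attempt in 1:10) {
      semiX <- sqrt(areaPx * aspect / pi)
      semiY <- sqrt(areaPx / (aspect * pi))
      poly <- blobBoundary(cx, cy, semiX, semiY, spec$boundaryWobble)
      inBounds <- all(poly[, "x"] >= 1 & poly[, "x"] <= nc - 2 &
                      poly[, "y"] >= 1 & poly[, "y"] <= nr - 2)
      if (inBounds) {
        m <- pointsInPolygonMask(poly, nr, nc)
        if (sum(m) >= 16) break
        m <- NULL
      }
      areaPx <- areaPx * 0.9^2
    }
    if (is.null(m)) stop("pancreas blob could not be placed within image bounds")
    m
  })

  envBg <- speckleEnvelope(c(nr, nc), spec$backgroundCorrelation,
                           deriveSeed(texSeed, 1L))
  clIn <- spec$baseCorrelation * spec$textureSmoothing
  envIn <- speckleEnvelope(c(nr, nc), clIn, deriveSeed(texSeed, 2L),
                           coherent = spec$coherentAmplitude)
  env <- envBg / mean(envBg)
  env[mask] <- (envIn / mean(envIn))[mask]

  g <- logCompress(env)
  rng <- range(g)
  img <- round(255 * (g - rng[1]) / diff(rng))
  img[mask] <- clamp(img[mask] + spec$echogenicityOffset, 0, 255)

  image <- methods::new("UltrasoundImage", pixels = img, spacing = sp,
                        patientId = NA_character_, classLabel = spec$classLabel)
  list(image = image,
       mask = methods::new("PancreasMask", mask = mask, regionLabel = "whole"),
       classLabel = spec$classLabel)
}

#' Cohort specification
#'
#' @param nDM,nNonDM number of phantoms per class (>= 1).
#' @param dmSpec,nonDmSpec per-class [phantomSpec()]s (seeds are overridden
#'   per phantom, derived from `masterSeed`).
#' @param masterSeed integer master seed.
#' @return a list of class `"CohortSpec"`.
#' @export
cohortSpec <- function(nDM, nNonDM,
                       dmSpec = phantomSpec("DM"),
                       nonDmSpec = phantomSpec("non-DM"),
                       masterSeed = 1) {
  if (nDM < 1 || nNonDM < 1) stop("nDM and nNonDM must each be >= 1")
  structure(list(nDM = as.integer(nDM), nNonDM = as.integer(nNonDM),
                 dmSpec = dmSpec, nonDmSpec = nonDmSpec,
                 masterSeed = as.integer(masterSeed)),
            class = "CohortSpec")
}

#' Generate a class-labelled synthetic cohort
#'
#' One phantom per synthetic patient; per-phantom seeds are derived
#' deterministically from the master seed, so the cohort is reproducible
#' and individual phantoms can be regenerated in isolation.
#'
#' @param spec a [cohortSpec()].
#' @return list with `phantoms` (list of [generatePhantom()] results) and
#'   `metadata` (data.frame: id, dm_status, age, sex, n_images).
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  n <- spec$nDM + spec$nNonDM
  labels <- c(rep("DM", spec$nDM), rep("non-DM", spec$nNonDM))
  phantoms <- vector("list", n)
  for (i in seq_len(n)) {
    base <- if (labels[i] == "DM") spec$dmSpec else spec$nonDmSpec
    base$seed <- deriveSeed(spec$masterSeed, i, 1L)
    ph <- generatePhantom(base)
    ph$image@patientId <- sprintf("P%03d", i)
    phantoms[[i]] <- ph
  }
  meta <- withSeed(deriveSeed(spec$masterSeed, 0L), {
    data.frame(id = sprintf("P%03d", seq_len(n)),
               dm_status = labels,
               age = sample(2:18, n, replace = TRUE),
               sex = sample(c("M", "F"), n, replace = TRUE),
               n_images = 1L,
               stringsAsFactors = FALSE)
  })
  list(phantoms = phantoms, metadata = meta)
}

#' Write a cohort to disk (8-bit PNGs plus a metadata CSV)
#'
#' Images as grayscale PNG, masks as 0/255 PNG, metadata as CSV with
#' columns id, dm_status, age, sex, n_images.
#'
#' @param cohort result of [generateCohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the metadata data.frame with file path columns added.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- cohort$metadata
  meta$image_file <- file.path(dir, paste0(meta$id, ".png"))
  meta$mask_file <- file.path(dir, paste0(meta$id, "_mask.png"))
  for (i in seq_along(cohort$phantoms)) {
    ph <- cohort$phantoms[[i]]
    png::writePNG(pixels(ph$image) / 255, meta$image_file[i])
    png::writePNG(maskMatrix(ph$mask) * 1, meta$mask_file[i])
  }
  utils::write.csv(meta[, c("id", "dm_status", "age", "sex", "n_images")],
                   file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(meta)
}
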