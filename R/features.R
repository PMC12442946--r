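# Assembling the full per-image feature vector and cohort feature tables.

#' Feature extraction configuration
#'
#' @param glcmLevels GLCM quantisation levels.
#' @param glcmDistance GLCM offset distance, pixels.
#' @param glcmAngles GLCM offset angles, degrees.
#' @param lbpRadius,lbpPoints local binary pattern geometry.
#' @param siftContrast,siftEdgeRatio keypoint detector thresholds.
#' @return a list of class `"FeatureConfig"`.
#' @export
featureConfig <- function(glcmLevels = 32, glcmDistance = 1,
                          glcmAngles = c(0, 45, 90, 135),
                          lbpRadius = 1, lbpPoints = 8,
                          siftContrast = 0.03, siftEdgeRatio = 10) {
  structure(list(glcmLevels = glcmLevels, glcmDistance = glcmDistance,
                 glcmAngles = glcmAngles, lbpRadius = lbpRadius,
                 lbpPoints = lbpPoints, siftContrast = siftContrast,
                 siftEdgeRatio = siftEdgeRatio), class = "FeatureConfig")
}

#' Names of the canonical feature vector
#' @return character vector of the 23 feature names.
#' @export
featureNames <- function() {
  c("area", "perimeter", "centroid_x", "centroid_y", "aspect_ratio",
    "eccentricity", "intensity_entropy", "gradient_magnitude",
    "haralick_asm", "haralick_contrast", "haralick_correlation",
    "haralick_variance", "haralick_idm", "haralick_sum_average",
    "haralick_sum_variance", "haralick_entropy", "haralick_sum_entropy",
    "haralick_difference_entropy", "haralick_imc1", "haralick_imc2",
    "lbp_entropy", "lbp_energy", "sift_keypoints")
}

#' Extract the full morphology + texture feature vector for one image
#'
#' Populates every canonical feature ([featureNames()]). Degenerate
#' texture inputs (constant regions) propagate the documented limit
#' values (ASM = IDM = LBP energy = 1, entropies = 0) and are flagged
#' through the `degenerate` attribute so cohort tables stay rectangular.
#'
#' @param image an [UltrasoundImage-class].
#' @param mask a [PancreasMask-class] of the same shape (>= 16 foreground
#'   pixels).
#' @param config a [featureConfig()].
#' @return named numeric vector (length 23) with attribute `degenerate`
#'   naming any degenerate components.
#' @examples
#' ph <- generatePhantom(phantomSpec("non-DM", seed = 3))
#' fv <- extractFeatures(ph$image, ph$mask)
#' round(fv[c("area", "intensity_entropy", "lbp_energy")], 3)
#' @export
extractFeatures <- function(image, mask, config = featureConfig()) {
  m <- maskMatrix(mask)
  if (sum(m) < 16) stop("mask too small: at least 16 foreground pixels required")
  sp <- pixelSpacing(image)
  degenerate <- character()

  morph <- morphologyFeatures(mask, sp)
  glcm <- computeGLCM(image, mask, levels = config$glcmLevels,
                      distance = config$glcmDistance, angles = config$glcmAngles)
  har <- haralickFeatures(glcm)
  if (isTRUE(attr(har, "degenerate"))) degenerate <- c(degenerate, "glcm")
  ie <- intensityEntropy(image, mask)
  lbp <- tryCatch(lbpFeatures(image, mask, radius = config$lbpRadius,
                              points = config$lbpPoints),
                  error = function(e) {
                    degenerate <<- c(degenerate, "lbp")
                    list(energy = 1, entropy = 0)
                  })
  gm <- gradientMagnitude(image, mask)
  sk <- siftKeypointCount(image, mask, contrastThreshold = config$siftContrast,
                          edgeRatio = config$siftEdgeRatio)
  if (isTRUE(attr(sk, "degenerate"))) degenerate <- c(degenerate, "sift")

  out <- c(morph[c("area", "perimeter", "centroid_x", "centroid_y",
                   "aspect_ratio", "eccentricity")],
           intensity_entropy = ie,
           gradient_magnitude = gm,
           har[c("haralick_asm", "haralick_contrast", "haralick_correlation",
                 "haralick_variance", "haralick_idm", "haralick_sum_average",
                 "haralick_sum_variance", "haralick_entropy",
                 "haralick_sum_entropy", "haralick_difference_entropy",
                 "haralick_imc1", "haralick_imc2")],
           lbp_entropy = lbp$entropy,
           lbp_energy = lbp$energy,
           sift_keypoints = as.numeric(sk))
  names(out) <- featureNames()
  attr(out, "degenerate") <- degenerate
  attr(out, "centroid_col_px") <- attr(morph, "centroid_col_px")
  attr(out, "centroid_row_px") <- attr(morph, "centroid_row_px")
  out
}

#' Feature table for a synthetic cohort
#'
#' One row per phantom; feature columns per [featureNames()] plus id and
#' class label metadata.
#'
#' @param cohort result of [generateCohort()].
#' @param config a [featureConfig()].
#' @return data.frame.
#' @export
cohortFeatureTable <- function(cohort, config = featureConfig()) {
  rows <- lapply(seq_along(cohort$phantoms), function(i) {
    ph <- cohort$phantoms[[i]]
    fv <- extractFeatures(ph$image, ph$mask, config)
    cbind(data.frame(id = patientId(ph$image), dm_status = ph$classLabel,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv)))
  })
  do.call(rbind, rows)
}

#' Write a feature table as CSV
#' @param table data.frame from [cohortFeatureTable()].
#' @param path output file.
#' @export
writeFeatureCSV <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
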