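# Tissue property defaults and layered abdominal geometry sampling.

#' Acoustic and thermal tissue property defaults
#'
#' Acoustic properties (speed of sound, density, amplitude attenuation at
#' 1 MHz, specific heat) follow published therapeutic-ultrasound modelling
#' values for the abdominal beam path. Thermal conductivities are
#' literature placeholders chosen by this package (they are not part of
#' the acoustic property set) and perfusion defaults to zero because blood
#' is modelled as an explicit layer rather than a distributed sink.
#'
#' @return data.frame with one row per tissue type.
#' @export
tissueProperties <- function() {
  data.frame(
    name = c("skin", "muscle", "bowel", "blood", "pancreas"),
    speed_of_sound = c(1624, 1588.4, 1560, 1578, 1591),
    density = c(1109, 1090, 1000, 1050, 1087),
    attenuation_db_cm = c(3.5, 0.7, 0.002, 0.21, 0.829),
    specific_heat = c(3391, 3421, 4200, 3617, 3164),
    conductivity = c(0.37, 0.49, 0.55, 0.52, 0.51),
    perfusion = c(0, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

#' Build a tissue stack from named layer thicknesses
#'
#' @param thickness named numeric vector of thicknesses in cm, proximal
#'   first; names must appear in [tissueProperties()].
#' @param properties property table; defaults to [tissueProperties()].
#' @return a [TissueStack-class].
#' @examples
#' tissueStack(c(skin = 0.2, muscle = 1.3, pancreas = 2.5))
#' @export
tissueStack <- function(thickness, properties = tissueProperties()) {
  if (is.null(names(thickness)) || any(!nzchar(names(thickness))))
    stop("thickness must be a named vector")
  idx <- match(names(thickness), properties$name)
  if (anyNA(idx)) stop("unknown tissue: ",
                       paste(names(thickness)[is.na(idx)], collapse = ", "))
  L <- properties[idx, , drop = FALSE]
  L$thickness_cm <- as.numeric(thickness)
  rownames(L) <- NULL
  methods::new("TissueStack",
               layers = L[, c("name", "thickness_cm", "speed_of_sound",
                              "density", "attenuation_db_cm", "specific_heat",
                              "conductivity", "perfusion")])
}

#' Default five-layer abdominal stack
#'
#' skin 0.2, muscle 1.3, bowel 2.0, blood 0.5, pancreas 2.5 cm: the
#' pancreas proximal boundary sits 4.0 cm below the dermis and the total
#' depth (6.5 cm) stays inside the 7 cm axial domain used for solver
#' cross-validation.
#' @return a [TissueStack-class].
#' @export
defaultTissueStack <- function() {
  tissueStack(c(skin = 0.2, muscle = 1.3, bowel = 2.0,
                blood = 0.5, pancreas = 2.5))
}

#' Geometry specification for sampled abdominal stacks
#'
#' @param layerMeans,layerSds named vectors (cm) for the layers proximal to
#'   the pancreas, in beam order.
#' @param pancreasMean,pancreasSd pancreas layer thickness, cm.
#' @param depthRange allowed range for the pancreas proximal depth, cm.
#' @param seed integer seed.
#' @return a list of class `"GeometrySpec"`.
#' @export
geometrySpec <- function(layerMeans = c(skin = 0.2, muscle = 1.3,
                                        bowel = 2.0, blood = 0.5),
                         layerSds = c(skin = 0.04, muscle = 0.3,
                                      bowel = 0.5, blood = 0.15),
                         pancreasMean = 2.5, pancreasSd = 0.4,
                         depthRange = c(2, 6), seed = 1) {
  if (any(layerMeans <= 0) || pancreasMean <= 0)
    stop("layer thickness means must be > 0")
  if (depthRange[1] <= 0 || depthRange[2] <= depthRange[1])
    stop("depthRange must be increasing and positive")
  if (layerMeans[1] >= depthRange[2])
    stop("depth range incompatible with layer thicknesses")
  structure(list(layerMeans = layerMeans, layerSds = layerSds,
                 pancreasMean = pancreasMean, pancreasSd = pancreasSd,
                 depthRange = depthRange, seed = as.integer(seed)),
            class = "GeometrySpec")
}

#' @noRd
rtruncnorm1 <- function(mean, sd, lo) {
  for (i in 1:50) {
    x <- stats::rnorm(1, mean, sd)
    if (x > lo) return(x)
  }
  lo + abs(stats::rnorm(1, 0, sd))
}

#' Sample a layered abdominal geometry
#'
#' Thicknesses are drawn from truncated normals; if the resulting pancreas
#' proximal depth falls outside `depthRange`, the soft-tissue layers
#' between skin and pancreas are rescaled proportionally onto the nearest
#' bound, so the sampled proximal depth always lies in the requested range.
#'
#' @param spec a [geometrySpec()].
#' @return a [TissueStack-class].
#' @export
generateTissueStack <- function(spec) {
  stopifnot(inherits(spec, "GeometrySpec"))
  withSeed(spec$seed, {
    th <- mapply(function(m, s) rtruncnorm1(m, s, 0.02 * m + 0.01),
                 spec$layerMeans, spec$layerSds)
    names(th) <- names(spec$layerMeans)
    panc <- rtruncnorm1(spec$pancreasMean, spec$pancreasSd, 0.5)
    prox <- sum(th)
    lo <- spec$depthRange[1]; hi <- spec$depthRange[2]
    if (prox < lo || prox > hi) {
      target <- clamp(prox, lo, hi)
      soft <- setdiff(names(th), names(th)[1])  # skin kept fixed
      scale <- (target - th[1]) / (prox - th[1])
      if (!is.finite(scale) || scale <= 0)
        stop("depth range incompatible with sampled thicknesses")
      th[soft] <- th[soft] * scale
    }
    tissueStack(c(th, pancreas = panc))
  })
}
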