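# S4 containers for images, masks, tissue stacks, thermal fields and dose maps.

#' UltrasoundImage: a grayscale B-mode frame with physical pixel spacing
#'
#' Pixels are stored as a numeric matrix on the native 8-bit scale (0-255);
#' row 1 is the transducer/dermis side, so depth increases with row index.
#' Spacing is isotropic, in mm per pixel.
#'
#' @slot pixels numeric matrix, values in \[0, 255\].
#' @slot spacing positive scalar, mm per pixel.
#' @slot patientId character identifier (may be `NA`).
#' @slot classLabel one of `"DM"`, `"non-DM"`, `"unknown"`.
#' @export
setClass("UltrasoundImage",
  representation(pixels = "matrix", spacing = "numeric",
                 patientId = "character", classLabel = "character"),
  prototype(spacing = 1, patientId = NA_character_, classLabel = "unknown"))

setValidity("UltrasoundImage", function(object) {
  msg <- character()
  if (length(object@spacing) != 1 || !is.finite(object@spacing) || object@spacing <= 0)
    msg <- c(msg, "spacing must be a single positive number (mm/pixel)")
  if (!all(is.finite(object@pixels)))
    msg <- c(msg, "pixels must be finite")
  else if (min(object@pixels) < 0 || max(object@pixels) > 255)
    msg <- c(msg, "pixels must lie in [0, 255]")
  if (!object@classLabel %in% c("DM", "non-DM", "unknown"))
    msg <- c(msg, "classLabel must be 'DM', 'non-DM' or 'unknown'")
  if (length(msg)) msg else TRUE
})

#' PancreasMask: a binary region aligned to an ultrasound image
#'
#' @slot mask logical matrix (TRUE = inside the pancreas region).
#' @slot regionLabel one of `"head"`, `"body"`, `"tail"`, `"whole"`.
#' @export
setClass("PancreasMask",
  representation(mask = "matrix", regionLabel = "character"),
  prototype(regionLabel = "whole"))

setValidity("PancreasMask", function(object) {
  msg <- character()
  if (!is.logical(object@mask))
    msg <- c(msg, "mask must be a logical matrix")
  else if (!any(object@mask))
    msg <- c(msg, "mask must contain at least one foreground pixel")
  if (!object@regionLabel %in% c("head", "body", "tail", "whole"))
    msg <- c(msg, "regionLabel must be 'head', 'body', 'tail' or 'whole'")
  if (length(msg)) msg else TRUE
})

#' TissueStack: ordered layers on the acoustic beam path
#'
#' One row per layer, proximal (skin) first. Acoustic attenuation is an
#' amplitude coefficient in dB/cm at 1 MHz, assumed linear in frequency.
#' Thermal conductivity and perfusion are solver parameters with
#' configuration defaults; they are not part of the acoustic literature
#' table bundled with the package.
#'
#' @slot layers data.frame with columns `name`, `thickness_cm`,
#'   `speed_of_sound` (m/s), `density` (kg/m^3), `attenuation_db_cm`,
#'   `specific_heat` (J/kg/K), `conductivity` (W/m/K),
#'   `perfusion` (kg/m^3/s).
#' @export
setClass("TissueStack", representation(layers = "data.frame"))

setValidity("TissueStack", function(object) {
  need <- c("name", "thickness_cm", "speed_of_sound", "density",
            "attenuation_db_cm", "specific_heat", "conductivity", "perfusion")
  msg <- character()
  if (!all(need %in% names(object@layers)))
    msg <- c(msg, paste("layers must have columns:", paste(need, collapse = ", ")))
  else {
    L <- object@layers
    if (nrow(L) < 1) msg <- c(msg, "at least one layer required")
    pos <- c("thickness_cm", "speed_of_sound", "density", "specific_heat", "conductivity")
    for (col in pos) if (any(L[[col]] <= 0)) msg <- c(msg, paste(col, "must be > 0"))
    if (any(L$attenuation_db_cm < 0)) msg <- c(msg, "attenuation must be >= 0")
    if (any(L$perfusion < 0)) msg <- c(msg, "perfusion must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' TransducerSpec: circular therapeutic transducer
#'
#' @slot geometry `"focused"` or `"unfocused"`.
#' @slot activeDiameter active aperture diameter, cm.
#' @slot focalDepth geometric focal depth, cm (focused only; 2-8 cm).
#' @slot frequency centre frequency, MHz.
#' @export
setClass("TransducerSpec",
  representation(geometry = "character", activeDiameter = "numeric",
                 focalDepth = "numeric", frequency = "numeric"),
  prototype(geometry = "focused", activeDiameter = 1.5, focalDepth = 4,
            frequency = 1))

setValidity("TransducerSpec", function(object) {
  msg <- character()
  if (!object@geometry %in% c("focused", "unfocused"))
    msg <- c(msg, "geometry must be 'focused' or 'unfocused'")
  if (object@activeDiameter <= 0) msg <- c(msg, "activeDiameter must be > 0")
  if (object@frequency <= 0) msg <- c(msg, "frequency must be > 0")
  if (object@geometry == "focused" &&
      (object@focalDepth < 2 || object@focalDepth > 8))
    msg <- c(msg, "focused focalDepth must lie in [2, 8] cm")
  if (length(msg)) msg else TRUE
})

#' SonicationProtocol: exposure parameters
#'
#' @slot intensity surface intensity, W/cm^2.
#' @slot dutyFactor fraction of each pulse period with the source on, (0, 1].
#' @slot duration sonication time, minutes.
#' @slot pulsePeriod pulse repetition period, seconds.
#' @export
setClass("SonicationProtocol",
  representation(intensity = "numeric", dutyFactor = "numeric",
                 duration = "numeric", pulsePeriod = "numeric"),
  prototype(intensity = 5, dutyFactor = 1, duration = 3, pulsePeriod = 1))

setValidity("SonicationProtocol", function(object) {
  msg <- character()
  if (object@intensity < 0) msg <- c(msg, "intensity must be >= 0")
  if (object@dutyFactor <= 0 || object@dutyFactor > 1)
    msg <- c(msg, "dutyFactor must lie in (0, 1]")
  if (object@duration <= 0) msg <- c(msg, "duration must be > 0")
  if (object@pulsePeriod <= 0) msg <- c(msg, "pulsePeriod must be > 0")
  if (length(msg)) msg else TRUE
})

#' ThermalField: temperature history on an axisymmetric (r, z) mesh
#'
#' Temperatures are in degrees Celsius with a uniform 37 C baseline. Full
#' grid snapshots are stored at a configurable frame interval; the on-axis
#' (r = 0) profile is stored at every accepted time step together with the
#' running spatial maximum per node.
#'
#' @slot frames numeric array `[nr, nz, nframes]` of snapshots (C).
#' @slot frameTimes times of the snapshots, seconds.
#' @slot onAxis matrix `[nz, nsteps]`, on-axis temperature series.
#' @slot onAxisTimes times of the on-axis series, seconds.
#' @slot r,z node coordinates, metres.
#' @slot maxT matrix `[nr, nz]`, running maximum temperature per node.
#' @slot tissueIndex integer vector `[nz]`, layer index at each depth node.
#' @slot layerNames layer names matching `tissueIndex`.
#' @slot baseline baseline temperature, C.
#' @export
setClass("ThermalField",
  representation(frames = "array", frameTimes = "numeric",
                 onAxis = "matrix", onAxisTimes = "numeric",
                 r = "numeric", z = "numeric", maxT = "matrix",
                 tissueIndex = "integer", layerNames = "character",
                 baseline = "numeric"),
  prototype(baseline = 37))

setValidity("ThermalField", function(object) {
  msg <- character()
  if (!all(is.finite(object@frames))) msg <- c(msg, "frames must be finite")
  if (length(object@frameTimes) != dim(object@frames)[3])
    msg <- c(msg, "frameTimes length must match frames")
  if (any(object@frames < -273.15)) msg <- c(msg, "temperatures below absolute zero")
  if (length(msg)) msg else TRUE
})

#' DoseMap: CEM43 thermal dose per grid node
#'
#' @slot cem matrix `[nr, nz]` of cumulative equivalent minutes at 43 C.
#' @slot r,z node coordinates, metres.
#' @slot tissueIndex integer vector `[nz]`, layer index at each depth node.
#' @slot layerNames layer names matching `tissueIndex`.
#' @export
setClass("DoseMap",
  representation(cem = "matrix", r = "numeric", z = "numeric",
                 tissueIndex = "integer", layerNames = "character"))

setValidity("DoseMap", function(object) {
  if (any(object@cem < 0)) "CEM43 must be >= 0" else TRUE
})
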