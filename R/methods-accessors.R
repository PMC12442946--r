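# Accessor and show methods.

#' @rdname UltrasoundImage-class
#' @export
setMethod("pixels", "UltrasoundImage", function(x) x@pixels)

#' @rdname UltrasoundImage-class
#' @export
setMethod("pixelSpacing", "UltrasoundImage", function(x) x@spacing)

#' @rdname UltrasoundImage-class
#' @export
setMethod("patientId", "UltrasoundImage", function(x) x@patientId)

#' @rdname UltrasoundImage-class
#' @export
setMethod("classLabel", "UltrasoundImage", function(x) x@classLabel)

#' @rdname PancreasMask-class
#' @export
setMethod("maskMatrix", "PancreasMask", function(x) x@mask)

#' @rdname PancreasMask-class
#' @export
setMethod("regionLabel", "PancreasMask", function(x) x@regionLabel)

#' @rdname TissueStack-class
#' @export
setMethod("layers", "TissueStack", function(x) x@layers)

#' @rdname stackDepth
#' @export
setMethod("stackDepth", "TissueStack", function(x) sum(x@layers$thickness_cm))

#' @rdname layerProximalDepth
#' @export
setMethod("layerProximalDepth", "TissueStack", function(x, name) {
  L <- x@layers
  i <- match(name, L$name)
  if (is.na(i)) stop("no layer named '", name, "'")
  if (i == 1) 0 else sum(L$thickness_cm[seq_len(i - 1)])
})

#' @rdname ThermalField-class
#' @export
setMethod("onAxisSeries", "ThermalField", function(x)
  list(times = x@onAxisTimes, z = x@z, temperature = x@onAxis))

#' @rdname ThermalField-class
#' @param tissue optional layer name; restrict to nodes in that layer.
#' @export
setMethod("peakTemperature", "ThermalField", function(x, tissue = NULL) {
  if (is.null(tissue)) return(max(x@maxT))
  i <- match(tissue, x@layerNames)
  if (is.na(i)) stop("no layer named '", tissue, "'")
  cols <- which(x@tissueIndex == i)
  if (!length(cols)) return(NA_real_)
  max(x@maxT[, cols])
})

#' @rdname DoseMap-class
#' @export
setMethod("cemMatrix", "DoseMap", function(x) x@cem)

#' @rdname DoseMap-class
#' @param tissue optional layer name; restrict to nodes in that layer.
#' @export
setMethod("peakDose", "DoseMap", function(x, tissue = NULL) {
  if (is.null(tissue)) return(max(x@cem))
  i <- match(tissue, x@layerNames)
  if (is.na(i)) stop("no layer named '", tissue, "'")
  cols <- which(x@tissueIndex == i)
  if (!length(cols)) return(NA_real_)
  max(x@cem[, cols])
})

setMethod("show", "UltrasoundImage", function(object) {
  d <- dim(object@pixels)
  cat("UltrasoundImage:", d[1], "x", d[2], "pixels,",
      object@spacing, "mm/px, patient", object@patientId,
      paste0("(", object@classLabel, ")"), "\n")
})

setMethod("show", "PancreasMask", function(object) {
  d <- dim(object@mask)
  cat("PancreasMask:", d[1], "x", d[2], "grid,",
      sum(object@mask), "foreground px, region", object@regionLabel, "\n")
})

setMethod("show", "TissueStack", function(object) {
  cat("TissueStack:", nrow(object@layers), "layers,",
      sprintf("%.2f", sum(object@layers$thickness_cm)), "cm total\n")
  print(object@layers[, c("name", "thickness_cm", "speed_of_sound",
                          "density", "attenuation_db_cm", "specific_heat")],
        row.names = FALSE)
})

setMethod("show", "TransducerSpec", function(object) {
  cat("TransducerSpec:", object@geometry, "circular,",
      object@activeDiameter, "cm aperture,",
      if (object@geometry == "focused") paste0("focal depth ", object@focalDepth, " cm,") else "",
      object@frequency, "MHz\n")
})

setMethod("show", "SonicationProtocol", function(object) {
  cat("SonicationProtocol:", object@intensity, "W/cm2, duty",
      object@dutyFactor, ",", object@duration, "min, pulse period",
      object@pulsePeriod, "s\n")
})

setMethod("show", "ThermalField", function(object) {
  cat("ThermalField:", length(object@r), "x", length(object@z),
      "(r x z) nodes,", length(object@frameTimes), "frames over",
      sprintf("%.0f", max(object@frameTimes)), "s; peak",
      sprintf("%.2f", max(object@maxT)), "C\n")
})

setMethod("show", "DoseMap", function(object) {
  cat("DoseMap:", length(object@r), "x", length(object@z),
      "(r x z) nodes; peak CEM43", sprintf("%.3g", max(object@cem)), "min\n")
})
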