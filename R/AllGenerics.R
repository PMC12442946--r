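# Generics and accessors. Slot access from user code should go through these.

#' @rdname UltrasoundImage-class
#' @param object,x an S4 object from this package.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname UltrasoundImage-class
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' @rdname UltrasoundImage-class
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @rdname UltrasoundImage-class
#' @export
setGeneric("classLabel", function(x) standardGeneric("classLabel"))

#' @rdname PancreasMask-class
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @rdname PancreasMask-class
#' @export
setGeneric("regionLabel", function(x) standardGeneric("regionLabel"))

#' @rdname TissueStack-class
#' @export
setGeneric("layers", function(x) standardGeneric("layers"))

#' Total stack depth in cm
#' @param x a [TissueStack-class].
#' @export
setGeneric("stackDepth", function(x) standardGeneric("stackDepth"))

#' Proximal (shallow) boundary of a named layer, cm
#' @param x a [TissueStack-class].
#' @param name layer name.
#' @export
setGeneric("layerProximalDepth", function(x, name) standardGeneric("layerProximalDepth"))

#' @rdname ThermalField-class
#' @export
setGeneric("onAxisSeries", function(x) standardGeneric("onAxisSeries"))

#' @rdname ThermalField-class
#' @export
setGeneric("peakTemperature", function(x, tissue = NULL) standardGeneric("peakTemperature"))

#' @rdname DoseMap-class
#' @export
setGeneric("cemMatrix", function(x) standardGeneric("cemMatrix"))

#' @rdname DoseMap-class
#' @export
setGeneric("peakDose", function(x, tissue = NULL) standardGeneric("peakDose"))
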