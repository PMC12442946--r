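# User-facing constructors for the simulation spec classes.

#' Create a transducer specification
#'
#' @param geometry `"focused"` or `"unfocused"`.
#' @param activeDiameter aperture diameter, cm.
#' @param focalDepth focal depth, cm (focused; 2-8 cm).
#' @param frequency MHz.
#' @return a [TransducerSpec-class].
#' @examples
#' transducerSpec("focused", focalDepth = 4)
#' @export
transducerSpec <- function(geometry = c("focused", "unfocused"),
                           activeDiameter = 1.5, focalDepth = 4,
                           frequency = 1) {
  methods::new("TransducerSpec", geometry = match.arg(geometry),
               activeDiameter = activeDiameter, focalDepth = focalDepth,
               frequency = frequency)
}

#' Create a sonication protocol
#'
#' @param intensity surface intensity, W/cm^2.
#' @param dutyFactor duty factor in (0, 1\].
#' @param duration sonication time, minutes.
#' @param pulsePeriod pulse repetition period, s.
#' @return a [SonicationProtocol-class].
#' @examples
#' sonicationProtocol(5, 0.5, 3)
#' @export
sonicationProtocol <- function(intensity = 5, dutyFactor = 1, duration = 3,
                               pulsePeriod = 1) {
  methods::new("SonicationProtocol", intensity = intensity,
               dutyFactor = dutyFactor, duration = duration,
               pulsePeriod = pulsePeriod)
}
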