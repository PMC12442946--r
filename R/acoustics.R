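# Linear acoustics for circular therapeutic transducers: attenuation through
# a layered stack, on-axis intensity (plane-piston or O'Neil focused bowl)
# and the volumetric heat source q = 2 * alpha * I.

#' Convert an amplitude attenuation coefficient from dB/cm to Np/m
#'
#' `alpha_Np/m = alpha_dB/cm * 100 * ln(10) / 20` (amplitude convention).
#'
#' @param alphaDbCm attenuation in dB/cm (>= 0).
#' @return attenuation in nepers per metre.
#' @examples
#' dbPerCmToNeperPerM(0.829)  # ~9.54 Np/m (pancreas at 1 MHz)
#' @export
dbPerCmToNeperPerM <- function(alphaDbCm) {
  if (any(alphaDbCm < 0)) stop("attenuation must be >= 0")
  alphaDbCm * 100 * log(10) / 20
}

#' Cumulative amplitude attenuation (dB) down to depth z
#' @noRd
cumAttenuationDb <- function(stack, z, frequency) {
  L <- layers(stack)
  bounds <- cumsum(L$thickness_cm)
  starts <- c(0, bounds[-length(bounds)])
  vapply(z, function(zz) {
    seg <- pmax(0, pmin(zz, bounds) - starts)
    sum(L$attenuation_db_cm * frequency * seg)
  }, 0)
}

#' Intensity transmission factor through the stack down to depth z
#'
#' Product over the traversed layer segments of
#' `10^(-2 * alpha_dB * f * d / 20)` (attenuation linear in frequency,
#' amplitude convention, hence the factor 2 for intensity).
#'
#' @param stack a [TissueStack-class].
#' @param z depth(s) in cm, within `[0, stackDepth(stack)]`.
#' @param frequency MHz.
#' @return intensity multiplier(s) in (0, 1\].
#' @export
attenuationFactor <- function(stack, z, frequency = 1) {
  if (any(z < 0 | z > stackDepth(stack) + 1e-9))
    stop("z must lie within the stack depth")
  10^(-2 * cumAttenuationDb(stack, z, frequency) / 20)
}

#' O'Neil on-axis pressure gain of a spherically curved circular radiator
#'
#' `|2 / (1 - z/F)| * |sin(k * delta(z) / 2)|` with
#' `delta = sqrt((z - h)^2 + a^2) - z` and bowl depth
#' `h = F - sqrt(F^2 - a^2)`; the removable singularity at the focus has
#' the limit `k * h` (the classical focal gain). Lossless, linear.
#' @noRd
oneilAxialGain <- function(z_m, focus_m, radius_m, k) {
  h <- focus_m - sqrt(focus_m^2 - radius_m^2)
  g <- numeric(length(z_m))
  for (idx in seq_along(z_m)) {
    z <- z_m[idx]
    denom <- 1 - z / focus_m
    if (abs(denom) < 1e-9) { g[idx] <- k * h; next }
    delta <- sqrt((z - h)^2 + radius_m^2) - z
    g[idx] <- abs(2 / denom) * abs(sin(k * delta / 2))
  }
  g
}

#' Axial intensity and radial beam envelope through a tissue stack
#'
#' On-axis intensity: for an unfocused piston, the plane-wave
#' approximation `I0 * attenuation(z)`; for a focused bowl, the O'Neil
#' on-axis gain squared times attenuation. The radial profile is a
#' Gaussian whose width at each plane conserves the transmitted beam
#' power `P(z) = I0 * pi * a^2 * attenuation(z)`:
#' `sigma^2(z) = P(z) / (2 pi I_axis(z))`, capped to `[sigmaMin, a]` so
#' near-field nulls do not blow the envelope up. Beam geometry uses a
#' single reference sound speed (1540 m/s).
#'
#' @param transducer a [TransducerSpec-class].
#' @param stack a [TissueStack-class].
#' @param protocol a [SonicationProtocol-class] (supplies the surface
#'   intensity; duty gating is applied by the solver, not here).
#' @param z depths in cm; defaults to a 0.05 cm grid over the stack.
#' @param sigmaMin lower cap for the Gaussian radius, cm.
#' @return data.frame: `z_cm`, `intensity_wcm2` (on-axis, attenuated,
#'   duty NOT applied), `sigma_cm`, `power_w`.
#' @export
axialIntensity <- function(transducer, stack, protocol,
                           z = seq(0, stackDepth(stack), by = 0.05),
                           sigmaMin = 0.05) {
  a_cm <- transducer@activeDiameter / 2
  I0 <- protocol@intensity
  att <- attenuationFactor(stack, z, transducer@frequency)
  P <- I0 * pi * a_cm^2 * att
  if (transducer@geometry == "focused") {
    if (transducer@focalDepth > stackDepth(stack))
      warning("focal depth lies beyond the tissue stack; continuing")
    cRef <- 1540
    k <- 2 * pi * transducer@frequency * 1e6 / cRef   # 1/m
    gain <- oneilAxialGain(z / 100, transducer@focalDepth / 100, a_cm / 100, k)
    I <- I0 * gain^2 * att
  } else {
    I <- I0 * att
  }
  sigma <- ifelse(I > 0, sqrt(P / (2 * pi * pmax(I, 1e-12))), a_cm)
  sigma <- clamp(sigma, sigmaMin, a_cm)
  data.frame(z_cm = z, intensity_wcm2 = I, sigma_cm = sigma, power_w = P)
}

#' Cell-averaged axial source profile for the bioheat solvers
#'
#' The O'Neil on-axis intensity oscillates on a sub-millimetre scale in
#' the near field, so point sampling on a solver grid aliases the
#' deposited energy. This helper averages [axialIntensity()] over `nSub`
#' sub-points within each axial cell, so any mesh receives the same
#' deposited power per cell.
#' @noRd
axialSourceAveraged <- function(transducer, stack, protocol, z, dz, nSub = 10) {
  zmax <- stackDepth(stack)
  offs <- (seq_len(nSub) - 0.5) / nSub - 0.5
  Isum <- numeric(length(z)); Psum <- numeric(length(z))
  for (o in offs) {
    zs <- clamp(z + o * dz, 0, zmax)
    ax <- axialIntensity(transducer, stack, protocol, z = zs)
    Isum <- Isum + ax$intensity_wcm2
    Psum <- Psum + ax$power_w
  }
  I <- Isum / nSub; P <- Psum / nSub
  a_cm <- transducer@activeDiameter / 2
  sigma <- ifelse(I > 0, sqrt(P / (2 * pi * pmax(I, 1e-12))), a_cm)
  sigma <- clamp(sigma, 0.05, a_cm)
  list(intensity_wcm2 = I, sigma_cm = sigma, power_w = P)
}

#' Volumetric acoustic heat source
#'
#' `q = 2 * alpha_Np/m * I * duty` with I converted from W/cm^2 to W/m^2;
#' the duty factor applies time-averaged gating.
#'
#' @param intensity on-axis intensity, W/cm^2.
#' @param layer one row of [tissueProperties()] (needs
#'   `attenuation_db_cm`).
#' @param duty duty factor in (0, 1\].
#' @param frequency MHz.
#' @return heat source in W/m^3.
#' @export
heatSource <- function(intensity, layer, duty = 1, frequency = 1) {
  alpha <- dbPerCmToNeperPerM(layer$attenuation_db_cm * frequency)
  2 * alpha * intensity * 1e4 * duty
}
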