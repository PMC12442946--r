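# Explicit finite-difference Pennes bioheat solver on an axisymmetric
# (r, z) mesh. Layer properties vary along z; conduction uses harmonic-mean
# interface conductivities in z and the conservative cylindrical stencil in
# r (with the symmetric 4k/dr^2 form on the axis).

#' Simulation grid for the bioheat solvers
#'
#' @param dr,dz node spacing, cm.
#' @param rMax radial extent, cm.
#' @param zMax axial extent, cm; `NULL` uses the stack depth.
#' @return list of class `"BioheatGrid"`.
#' @export
bioheatGrid <- function(dr = 0.05, dz = 0.05, rMax = 4, zMax = NULL) {
  if (dr <= 0 || dz <= 0 || rMax <= 0) stop("grid spacings must be > 0")
  structure(list(dr = dr, dz = dz, rMax = rMax, zMax = zMax),
            class = "BioheatGrid")
}

#' Solver options
#'
#' @param boundary `"dirichlet"` (all outer boundaries pinned at the
#'   baseline) or `"insulated"` (zero flux; used for energy-balance
#'   checks).
#' @param conduction,perfusion logical switches (disabling conduction
#'   gives the lumped-heating limit used for validation).
#' @param gating `"averaged"` (duty applied as a time-averaged source) or
#'   `"explicit"` (on/off switching at the protocol pulse period).
#' @param dt requested time step, s; `NULL` selects the stability limit.
#'   Unstable requests are reduced with a warning.
#' @param frameInterval spacing of stored full-grid snapshots, s.
#' @param baseline baseline temperature, C.
#' @param initial optional initial temperature matrix `[nr, nz]`.
#' @param qField optional heat-source override `[nr, nz]`, W/m^3
#'   (duty already applied); bypasses the acoustic model.
#' @return list of class `"BioheatOptions"`.
#' @export
bioheatOptions <- function(boundary = c("dirichlet", "insulated"),
                           conduction = TRUE, perfusion = TRUE,
                           gating = c("averaged", "explicit"),
                           dt = NULL, frameInterval = 1, baseline = 37,
                           initial = NULL, qField = NULL) {
  structure(list(boundary = match.arg(boundary), conduction = conduction,
                 perfusion = perfusion, gating = match.arg(gating),
                 dt = dt, frameInterval = frameInterval, baseline = baseline,
                 initial = initial, qField = qField),
            class = "BioheatOptions")
}

#' Layer index for each z node (cm); z = 0 belongs to the first layer
#' @noRd
tissueIndexAt <- function(stack, z_cm) {
  bounds <- cumsum(layers(stack)$thickness_cm)
  idx <- findInterval(z_cm, c(0, bounds[-length(bounds)]))
  as.integer(pmin(pmax(idx, 1L), nrow(layers(stack))))
}

#' Solve the Pennes bioheat equation for a sonication
#'
#' `rho c dT/dt = div(k grad T) - w_b c_blood (T - Tb) + q` with an
#' explicit (forward Euler) scheme, fixed 37 C initial condition, and the
#' acoustic source from [axialIntensity()] / [heatSource()] spread over
#' the energy-conserving Gaussian radial envelope. The time step is
#' auto-computed from the explicit stability limit (safety factor 0.8).
#'
#' @param stack a [TissueStack-class].
#' @param transducer a [TransducerSpec-class].
#' @param protocol a [SonicationProtocol-class].
#' @param grid a [bioheatGrid()].
#' @param options a [bioheatOptions()].
#' @return a [ThermalField-class].
#' @export
solveBioheat <- function(stack, transducer, protocol,
                         grid = bioheatGrid(), options = bioheatOptions()) {
  dr <- grid$dr / 100; dz <- grid$dz / 100           # m
  zMax <- (grid$zMax %||% stackDepth(stack)) / 100
  rMax <- grid$rMax / 100
  r <- seq(0, rMax, by = dr); nr <- length(r)
  z <- seq(0, zMax, by = dz); nz <- length(z)
  L <- layers(stack)
  ti <- tissueIndexAt(stack, z * 100)
  kz <- L$conductivity[ti]
  rhoc <- L$density[ti] * L$specific_heat[ti]
  wcb <- if (options$perfusion) L$perfusion[ti] * 3617 else rep(0, nz)
  Tb <- options$baseline

  # volumetric source (duty-averaged), W/m^3
  duty <- protocol@dutyFactor
  if (is.null(options$qField)) {
    ax <- axialSourceAveraged(transducer, stack, protocol, z * 100, grid$dz)
    alpha <- dbPerCmToNeperPerM(L$attenuation_db_cm[ti] * transducer@frequency)
    qAxis <- 2 * alpha * ax$intensity_wcm2 * 1e4      # W/m^3 on axis, duty 1
    sig <- ax$sigma_cm / 100
    Q <- outer(r, seq_len(nz), function(rr, jj) exp(-rr^2 / (2 * sig[jj]^2)))
    Q <- Q * matrix(qAxis, nr, nz, byrow = TRUE) * duty
  } else {
    Q <- options$qField
    stopifnot(all(dim(Q) == c(nr, nz)))
  }

  alphaT <- kz / rhoc
  coefMax <- max((4 / dr^2 + 2 / dz^2) * alphaT + wcb / rhoc)
  dtMax <- 0.8 / coefMax
  dt <- options$dt %||% dtMax
  if (dt > dtMax) {
    warning(sprintf("requested dt = %.3g s unstable; reduced to %.3g s", dt, dtMax))
    dt <- dtMax
  }
  durS <- protocol@duration * 60
  nSteps <- max(1L, as.integer(ceiling(durS / dt)))
  dt <- durS / nSteps

  # precomputed coefficient matrices
  RhoC <- matrix(rhoc, nr, nz, byrow = TRUE)
  Kz <- matrix(kz, nr, nz, byrow = TRUE)
  Wcb <- matrix(wcb, nr, nz, byrow = TRUE)
  kzp <- c((2 * kz[-nz] * kz[-1]) / (kz[-nz] + kz[-1]), 0)  # j to j+1
  KzpM <- matrix(kzp, nr, nz, byrow = TRUE)
  iInt <- 2:(nr - 1)
  ap <- (r[iInt] + dr / 2) / r[iInt]
  am <- (r[iInt] - dr / 2) / r[iInt]

  insul <- options$boundary == "insulated"
  Tm <- options$initial %||% matrix(Tb, nr, nz)
  stopifnot(all(dim(Tm) == c(nr, nz)))

  frameEvery <- max(1L, as.integer(round(options$frameInterval / dt)))
  frameIdx <- unique(c(seq(0L, nSteps, by = frameEvery), nSteps))
  frames <- array(NA_real_, c(nr, nz, length(frameIdx)))
  frameTimes <- frameIdx * dt
  onAxis <- matrix(NA_real_, nz, nSteps + 1L)
  frames[, , 1] <- Tm
  onAxis[, 1] <- Tm[1, ]
  maxT <- Tm
  fI <- 2L

  explicitGate <- options$gating == "explicit"
  pp <- protocol@pulsePeriod

  for (s in seq_len(nSteps)) {
    lap <- matrix(0, nr, nz)
    if (options$conduction) {
      # radial
      lap[1, ] <- 4 * (Tm[2, ] - Tm[1, ]) / dr^2
      lap[iInt, ] <- (ap * (Tm[iInt + 1, ] - Tm[iInt, ]) -
                      am * (Tm[iInt, ] - Tm[iInt - 1, ])) / dr^2
      if (insul) lap[nr, ] <- -((r[nr] - dr / 2) / r[nr]) *
          (Tm[nr, ] - Tm[nr - 1, ]) / dr^2
      lap <- Kz * lap
      # axial
      jC <- 2:(nz - 1)
      lap[, jC] <- lap[, jC] +
        (KzpM[, jC] * (Tm[, jC + 1] - Tm[, jC]) -
         KzpM[, jC - 1] * (Tm[, jC] - Tm[, jC - 1])) / dz^2
      if (insul) {
        lap[, 1] <- lap[, 1] + KzpM[, 1] * (Tm[, 2] - Tm[, 1]) / dz^2
        lap[, nz] <- lap[, nz] - KzpM[, nz - 1] * (Tm[, nz] - Tm[, nz - 1]) / dz^2
      }
    }
    qNow <- if (!explicitGate) Q
            else if (((s - 1) * dt) %% pp < duty * pp) Q / duty else Q * 0
    Tm <- Tm + dt * (lap + qNow - Wcb * (Tm - Tb)) / RhoC
    if (!insul) {
      Tm[nr, ] <- Tb; Tm[, 1] <- Tb; Tm[, nz] <- Tb
    }
    if (!all(is.finite(Tm))) stop("non-finite temperature: aborting")
    maxT <- pmax(maxT, Tm)
    onAxis[, s + 1L] <- Tm[1, ]
    if (fI <= length(frameIdx) && s == frameIdx[fI]) {
      frames[, , fI] <- Tm
      fI <- fI + 1L
    }
  }
  methods::new("ThermalField", frames = frames, frameTimes = frameTimes,
               onAxis = onAxis, onAxisTimes = (0:nSteps) * dt,
               r = r, z = z, maxT = maxT, tissueIndex = ti,
               layerNames = L$name, baseline = Tb)
}
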