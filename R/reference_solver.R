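# Independent reference bioheat solver used for cross-validation of
# solveBioheat(). Deliberately a separate implementation: finite-volume
# face fluxes on a finer mesh with ghost padding, rather than the nodal
# stencil of the main solver. Both discretise the same continuum problem,
# so the on-axis RMSE between them measures discretisation error only.

#' Reference Pennes bioheat solver (fine-grid finite-volume formulation)
#'
#' Control-volume discretisation: each node owns an annular cell; radial
#' and axial face fluxes are computed explicitly (harmonic-mean face
#' conductivity in z) and divergenced, with ghost cells implementing the
#' boundary condition. The default mesh halves the main solver's spacing.
#'
#' @inheritParams solveBioheat
#' @param grid a [bioheatGrid()]; default 0.025 cm spacing.
#' @param options a [bioheatOptions()]; `frameInterval` defaults to 5 s
#'   here (the on-axis series is still stored at every step).
#' @return a [ThermalField-class].
#' @export
referenceSolver <- function(stack, transducer, protocol,
                            grid = bioheatGrid(dr = 0.025, dz = 0.025),
                            options = bioheatOptions(frameInterval = 5)) {
  dr <- grid$dr / 100; dz <- grid$dz / 100
  zMax <- (grid$zMax %||% stackDepth(stack)) / 100
  rMax <- grid$rMax / 100
  r <- seq(0, rMax, by = dr); nr <- length(r)
  z <- seq(0, zMax, by = dz); nz <- length(z)
  L <- layers(stack)
  ti <- tissueIndexAt(stack, z * 100)
  kvec <- L$conductivity[ti]
  rhocvec <- L$density[ti] * L$specific_heat[ti]
  wcbvec <- if (options$perfusion) L$perfusion[ti] * 3617 else rep(0, nz)
  Tb <- options$baseline

  duty <- protocol@dutyFactor
  if (is.null(options$qField)) {
    ax <- axialSourceAveraged(transducer, stack, protocol, z * 100, grid$dz)
    alpha <- dbPerCmToNeperPerM(L$attenuation_db_cm[ti] * transducer@frequency)
    qAxis <- 2 * alpha * ax$intensity_wcm2 * 1e4 * duty
    sig <- ax$sigma_cm / 100
    Q <- outer(r, seq_len(nz), function(rr, jj) exp(-rr^2 / (2 * sig[jj]^2))) *
      matrix(qAxis, nr, nz, byrow = TRUE)
  } else {
    Q <- options$qField
  }

  alphaT <- kvec / rhocvec
  dtMax <- 0.7 / max((4 / dr^2 + 2 / dz^2) * alphaT + wcbvec / rhocvec)
  dt <- min(options$dt %||% dtMax, dtMax)
  durS <- protocol@duration * 60
  nSteps <- max(1L, as.integer(ceiling(durS / dt)))
  dt <- durS / nSteps

  insul <- options$boundary == "insulated"
  # face radii and per-cell geometric factors (finite-volume, cylindrical)
  rFaceP <- r + dr / 2                     # outer face of cell i
  rFaceM <- pmax(r - dr / 2, 0)            # inner face
  cellA <- (rFaceP^2 - rFaceM^2) / 2       # swept area / (2 pi), per unit dz
  # axial face conductivities between columns j and j+1
  kFaceZ <- 2 * kvec[-nz] * kvec[-1] / (kvec[-nz] + kvec[-1])
  KfZ <- matrix(kFaceZ, nr, nz - 1, byrow = TRUE)
  Kmat <- matrix(kvec, nr, nz, byrow = TRUE)
  RhoC <- matrix(rhocvec, nr, nz, byrow = TRUE)
  Wcb <- matrix(wcbvec, nr, nz, byrow = TRUE)

  Tcur <- options$initial %||% matrix(Tb, nr, nz)
  frameEvery <- max(1L, as.integer(round(options$frameInterval / dt)))
  frameIdx <- unique(c(seq(0L, nSteps, by = frameEvery), nSteps))
  frames <- array(NA_real_, c(nr, nz, length(frameIdx)))
  frames[, , 1] <- Tcur
  onAxis <- matrix(NA_real_, nz, nSteps + 1L)
  onAxis[, 1] <- Tcur[1, ]
  maxT <- Tcur
  fI <- 2L
  conduction <- options$conduction
  explicitGate <- options$gating == "explicit"
  pp <- protocol@pulsePeriod

  for (s in seq_len(nSteps)) {
    div <- matrix(0, nr, nz)
    if (conduction) {
      # radial face fluxes: F[i] across face between cells i and i+1,
      # per unit circumferential angle and unit dz: rFace * k * dT/dr
      dTr <- (Tcur[-1, ] - Tcur[-nr, ]) / dr
      Fr <- (rFaceP[-nr] * dTr) * Kmat[-nr, ]
      div[-c(1, nr), ] <- (Fr[-1, ] - Fr[-(nr - 1), ]) / cellA[-c(1, nr)]
      div[1, ] <- Fr[1, ] / cellA[1]
      if (insul) div[nr, ] <- -Fr[nr - 1, ] / cellA[nr]
      # (Dirichlet boundary nodes are re-pinned after the update)
      # axial face fluxes
      dTz <- (Tcur[, -1] - Tcur[, -nz]) / dz
      Fz <- KfZ * dTz
      div[, -c(1, nz)] <- div[, -c(1, nz)] + (Fz[, -1] - Fz[, -(nz - 1)]) / dz
      if (insul) {
        div[, 1] <- div[, 1] + Fz[, 1] / dz
        div[, nz] <- div[, nz] - Fz[, nz - 1] / dz
      }
    }
    qNow <- if (!explicitGate) Q
            else if (((s - 1) * dt) %% pp < duty * pp) Q / duty else Q * 0
    Tcur <- Tcur + dt * (div + qNow - Wcb * (Tcur - Tb)) / RhoC
    if (!insul) {
      Tcur[nr, ] <- Tb; Tcur[, 1] <- Tb; Tcur[, nz] <- Tb
    }
    if (!all(is.finite(Tcur))) stop("non-finite temperature in reference solver")
    maxT <- pmax(maxT, Tcur)
    onAxis[, s + 1L] <- Tcur[1, ]
    if (fI <= length(frameIdx) && s == frameIdx[fI]) {
      frames[, , fI] <- Tcur
      fI <- fI + 1L
    }
  }
  methods::new("ThermalField", frames = frames, frameTimes = frameIdx * dt,
               onAxis = onAxis, onAxisTimes = (0:nSteps) * dt,
               r = r, z = z, maxT = maxT, tissueIndex = ti,
               layerNames = L$name, baseline = Tb)
}
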