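# Bioheat solvers: equilibrium, lumped-heating oracle, energy balance,
# maximum principle, convergence and the dual-solver contract.

pancOnly <- function(depth = 2) tissueStack(c(pancreas = depth))

test_that("zero source stays at baseline everywhere", {
  st <- pancOnly()
  tu <- transducerSpec("unfocused")
  fld <- solveBioheat(st, tu, sonicationProtocol(0, 1, 0.2),
                      grid = bioheatGrid(dr = 0.1, dz = 0.1, rMax = 1))
  expect_equal(max(abs(fld@frames - 37)), 0)
  ref <- referenceSolver(st, tu, sonicationProtocol(0, 1, 0.2),
                         grid = bioheatGrid(dr = 0.1, dz = 0.1, rMax = 1))
  expect_equal(max(abs(ref@frames - 37)), 0)
})

test_that("lumped heating matches the closed form with conduction off", {
  # pancreas voxel under q = 2 alpha I at 5 W/cm2, duty 1:
  # dT after 10 s = q t / (rho c), within 1%
  st <- pancOnly(1)
  g <- bioheatGrid(dr = 0.1, dz = 0.1, rMax = 0.5)
  q <- 2 * dbPerCmToNeperPerM(0.829) * 5e4
  nrn <- length(seq(0, 0.5, by = 0.1)); nzn <- length(seq(0, 1, by = 0.1))
  opts <- bioheatOptions(boundary = "insulated", conduction = FALSE,
                         qField = matrix(q, nrn, nzn), dt = 0.05)
  pr <- sonicationProtocol(5, 1, 10 / 60)
  fld <- solveBioheat(st, transducerSpec(), pr, grid = g, options = opts)
  want <- 37 + q * 10 / (1087 * 3164)
  expect_equal(max(fld@frames[, , dim(fld@frames)[3]]), want, tolerance = 0.01)
  expect_equal(min(fld@frames[, , dim(fld@frames)[3]]), want, tolerance = 0.01)
  # the independent reference solver agrees with the same closed form
  ref <- referenceSolver(st, transducerSpec(), pr, grid = g, options = opts)
  expect_equal(max(ref@frames[, , dim(ref@frames)[3]]), want, tolerance = 0.01)
})

test_that("insulated-domain enthalpy rise equals deposited energy", {
  st <- pancOnly(1.5)
  g <- bioheatGrid(dr = 0.1, dz = 0.1, rMax = 1)
  r <- seq(0, 1, by = 0.1) / 100; z <- seq(0, 1.5, by = 0.1) / 100
  nrn <- length(r); nzn <- length(z)
  set.seed(2)
  Q <- matrix(runif(nrn * nzn, 0, 2e5), nrn, nzn)  # W/m^3
  opts <- bioheatOptions(boundary = "insulated", qField = Q)
  fld <- solveBioheat(st, transducerSpec(), sonicationProtocol(5, 1, 0.5),
                      grid = g, options = opts)
  dr <- 0.1 / 100; dz <- 0.1 / 100
  vol <- c(pi * (dr / 2)^2, 2 * pi * r[-1] * dr) * dz  # per-node volumes
  rhoc <- 1087 * 3164
  Tend <- fld@frames[, , dim(fld@frames)[3]]
  enthalpy <- sum(rhoc * (Tend - 37) * vol)
  deposited <- sum(Q * vol) * 30
  expect_equal(enthalpy, deposited, tolerance = 0.02)
})

test_that("with no source the maximum principle holds", {
  st <- pancOnly(1)
  g <- bioheatGrid(dr = 0.1, dz = 0.1, rMax = 1)
  nrn <- 11; nzn <- 11
  init <- matrix(37, nrn, nzn); init[5:7, 5:7] <- 60
  for (bc in c("dirichlet", "insulated")) {
    opts <- bioheatOptions(boundary = bc, initial = init,
                           qField = matrix(0, nrn, nzn))
    fld <- solveBioheat(st, transducerSpec(), sonicationProtocol(0, 1, 0.3),
                        grid = g, options = opts)
    expect_lte(max(fld@frames), 60 + 1e-9)
    expect_gte(min(fld@frames), 37 - 1e-9)
    # the peak decays monotonically over the stored frames
    peaks <- apply(fld@frames, 3, max)
    expect_true(all(diff(peaks) <= 1e-9))
  }
})

test_that("an unstable requested time step is reduced with a warning", {
  st <- pancOnly(1)
  g <- bioheatGrid(dr = 0.1, dz = 0.1, rMax = 0.5)
  expect_warning(
    fld <- solveBioheat(st, transducerSpec("unfocused"),
                        sonicationProtocol(1, 1, 0.05),
                        grid = g, options = bioheatOptions(dt = 50)),
    "unstable")
  expect_true(all(is.finite(fld@frames)))
})

test_that("halving the grid changes the focused peak by under 2%", {
  st <- defaultTissueStack()
  td <- transducerSpec("focused", focalDepth = 4)
  pr <- sonicationProtocol(5, 0.5, 0.5)  # 30 s
  f1 <- solveBioheat(st, td, pr, grid = bioheatGrid(dr = 0.05, dz = 0.05))
  f2 <- solveBioheat(st, td, pr, grid = bioheatGrid(dr = 0.025, dz = 0.025))
  rise1 <- peakTemperature(f1) - 37
  rise2 <- peakTemperature(f2) - 37
  expect_lt(abs(rise1 - rise2) / rise2, 0.02)
})

test_that("time-averaged and explicit duty gating deposit the same energy", {
  st <- pancOnly(1)
  g <- bioheatGrid(dr = 0.1, dz = 0.1, rMax = 0.5)
  nrn <- 6; nzn <- 11
  Q <- matrix(5e5, nrn, nzn)
  pr <- sonicationProtocol(5, 0.5, 0.5, pulsePeriod = 1)
  oAvg <- bioheatOptions(boundary = "insulated", conduction = FALSE,
                         qField = Q * 0.5, dt = 0.025)
  oGate <- bioheatOptions(boundary = "insulated", conduction = FALSE,
                          gating = "explicit", qField = Q * 0.5, dt = 0.025)
  fa <- solveBioheat(st, transducerSpec(), pr, grid = g, options = oAvg)
  fg <- solveBioheat(st, transducerSpec(), pr, grid = g, options = oGate)
  endA <- fa@frames[1, 1, dim(fa@frames)[3]]
  endG <- fg@frames[1, 1, dim(fg@frames)[3]]
  expect_equal(endA, endG, tolerance = 1e-6)
})

test_that("superficial layers out-heat the pancreas under unfocused exposure", {
  st <- defaultTissueStack()
  f <- solveBioheat(st, transducerSpec("unfocused"),
                    sonicationProtocol(5, 1, 3))
  expect_gt(max(peakTemperature(f, "skin"), peakTemperature(f, "muscle")),
            peakTemperature(f, "pancreas"))
})

test_that("the reference solver is an independent but consistent discretisation", {
  st <- defaultTissueStack()
  td <- transducerSpec("focused", focalDepth = 4)
  pr <- sonicationProtocol(5, 0.5, 0.3)
  a <- solveBioheat(st, td, pr, grid = bioheatGrid(dr = 0.05, dz = 0.05))
  b <- referenceSolver(st, td, pr, grid = bioheatGrid(dr = 0.05, dz = 0.05))
  # same mesh: different code paths agree closely but not bit-identically
  expect_lt(rmseBetweenFields(a, b), 0.05)
  expect_false(identical(a@onAxis, b@onAxis))
})
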