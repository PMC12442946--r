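# Speckle model, phantom generation, cohort assembly, geometry sampling.

test_that("speckle generator is deterministic and respects its contract", {
  a <- generateSpeckle(c(64, 64), correlationLength = 1.5, seed = 9)
  b <- generateSpeckle(c(64, 64), correlationLength = 1.5, seed = 9)
  expect_identical(a, b)
  expect_equal(dim(a), c(64L, 64L))
  expect_true(min(a) >= 0 && max(a) <= 255)
  expect_error(generateSpeckle(c(4, 64), seed = 1), "shape")
  expect_error(generateSpeckle(c(64, 64), correlationLength = -1), "correlationLength")
})

test_that("uncorrelated pre-log envelope has Rayleigh mean/sd ratio", {
  # Monte-Carlo oracle: Rayleigh mean/sd = sqrt(pi/2) / sqrt(2 - pi/2)
  rayleighRatio <- local({
    set.seed(123)
    r <- sqrt(rnorm(4e5)^2 + rnorm(4e5)^2)
    mean(r) / sd(r)
  })
  expect_equal(rayleighRatio, sqrt(pi / 2) / sqrt(2 - pi / 2), tolerance = 0.01)
  env <- speckleEnvelope(c(256, 256), correlationLength = 0, seed = 4)
  expect_equal(mean(env) / sd(env), rayleighRatio, tolerance = 0.02)
})

test_that("coherent component narrows the relative envelope spread", {
  cv0 <- with(list(e = speckleEnvelope(c(128, 128), 0, 5, coherent = 0)),
              sd(e) / mean(e))
  cv2 <- with(list(e = speckleEnvelope(c(128, 128), 0, 5, coherent = 2.5)),
              sd(e) / mean(e))
  expect_lt(cv2, cv0)
})

test_that("phantoms are reproducible and carry a valid mask", {
  sp <- phantomSpec("DM", seed = 21)
  a <- generatePhantom(sp)
  b <- generatePhantom(sp)
  expect_identical(pixels(a$image), pixels(b$image))
  expect_identical(maskMatrix(a$mask), maskMatrix(b$mask))
  expect_s4_class(a$image, "UltrasoundImage")
  expect_true(sum(maskMatrix(a$mask)) >= 16)
  expect_identical(a$classLabel, "DM")
  # mask stays inside the frame
  m <- maskMatrix(a$mask)
  expect_false(any(m[1, ]) || any(m[nrow(m), ]) || any(m[, 1]) || any(m[, ncol(m)]))
})

test_that("default class effects move features in the encoded directions", {
  # Monte-Carlo check of the built-in effect directions: DM phantoms have
  # higher LBP energy and lower intensity entropy than non-DM phantoms.
  n <- 8
  dm <- sapply(seq_len(n), function(i) {
    ph <- generatePhantom(phantomSpec("DM", seed = deriveSeed(301, i)))
    c(lbpFeatures(ph$image, ph$mask)$energy,
      intensityEntropy(ph$image, ph$mask))
  })
  nd <- sapply(seq_len(n), function(i) {
    ph <- generatePhantom(phantomSpec("non-DM", seed = deriveSeed(302, i)))
    c(lbpFeatures(ph$image, ph$mask)$energy,
      intensityEntropy(ph$image, ph$mask))
  })
  expect_gt(mean(dm[1, ]), mean(nd[1, ]))  # LBP energy higher in DM
  expect_lt(mean(dm[2, ]), mean(nd[2, ]))  # intensity entropy lower in DM
})

test_that("null construction makes the classes exchangeable", {
  # identical generating parameters -> the class label carries no signal;
  # a two-sample t-test on one texture feature behaves like a null test
  a <- sapply(1:6, function(i) {
    ph <- generatePhantom(nullPhantomSpec("DM", deriveSeed(11, i)))
    intensityEntropy(ph$image, ph$mask)
  })
  b <- sapply(1:6, function(i) {
    ph <- generatePhantom(nullPhantomSpec("non-DM", deriveSeed(12, i)))
    intensityEntropy(ph$image, ph$mask)
  })
  expect_gt(twoSampleTTest(a, b)$p, 0.001)
})

test_that("cohort generation mirrors the repository structure", {
  cs <- cohortSpec(11, 11, masterSeed = 5)
  co <- generateCohort(cs)
  expect_equal(nrow(co$metadata), 22)
  expect_equal(sum(co$metadata$dm_status == "DM"), 11)
  expect_named(co$metadata, c("id", "dm_status", "age", "sex", "n_images"))
  expect_error(cohortSpec(0, 5), "nDM")
  co2 <- generateCohort(cs)
  expect_identical(pixels(co$phantoms[[3]]$image), pixels(co2$phantoms[[3]]$image))
})

test_that("written cohorts round-trip through PNG and CSV", {
  dir <- withr::local_tempdir()
  cs <- cohortSpec(2, 2,
                   dmSpec = nullPhantomSpec("DM", 1),
                   nonDmSpec = nullPhantomSpec("non-DM", 1), masterSeed = 3)
  co <- generateCohort(cs)
  writeCohort(co, dir)
  meta <- read.csv(file.path(dir, "metadata.csv"))
  expect_equal(nrow(meta), 4)
  img <- loadUltrasound(file.path(dir, "P001.png"), spacingOverride = 0.8)
  expect_equal(pixels(img), pixels(co$phantoms[[1]]$image), ignore_attr = TRUE)
  msk <- readMaskPNG(file.path(dir, "P001_mask.png"))
  expect_identical(maskMatrix(msk), maskMatrix(co$phantoms[[1]]$mask))
})

test_that("sampled tissue stacks keep the pancreas in the requested depth window", {
  # sampling oracle over many draws: proximal depth always within [2, 6] cm
  prox <- vapply(1:1000, function(i) {
    st <- generateTissueStack(geometrySpec(seed = i))
    layerProximalDepth(st, "pancreas")
  }, 0)
  expect_true(all(prox >= 2 & prox <= 6))
  expect_gt(sd(prox), 0)  # genuinely random
  # determinism
  s1 <- generateTissueStack(geometrySpec(seed = 77))
  s2 <- generateTissueStack(geometrySpec(seed = 77))
  expect_identical(layers(s1), layers(s2))
})

test_that("degenerate single-layer stack works and invalid specs fail", {
  st <- tissueStack(c(pancreas = 1.7))
  expect_equal(stackDepth(st), 1.7)
  expect_equal(nrow(layers(st)), 1)
  expect_error(tissueStack(c(gristle = 1)), "unknown tissue")
  expect_error(geometrySpec(layerMeans = c(skin = 7)), "incompatible")
})

test_that("tissue property defaults match the modelling literature table", {
  tp <- tissueProperties()
  panc <- tp[tp$name == "pancreas", ]
  expect_equal(panc$speed_of_sound, 1591)
  expect_equal(panc$density, 1087)
  expect_equal(panc$attenuation_db_cm, 0.829)
  expect_equal(panc$specific_heat, 3164)
  expect_equal(tp$attenuation_db_cm[tp$name == "skin"], 3.5)
  expect_equal(tp$specific_heat[tp$name == "bowel"], 4200)
})
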