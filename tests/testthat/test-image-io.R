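# Loading, rasterization, isolation and depth descriptors.

test_that("PNG loading honours the spacing override and errors without one", {
  f <- withr::local_tempfile(fileext = ".png")
  mat <- matrix(seq(0, 1, length.out = 20 * 12), 20, 12)
  png::writePNG(mat, f)
  img <- loadUltrasound(f, spacingOverride = 0.2)
  expect_equal(pixelSpacing(img), 0.2)
  expect_equal(dim(pixels(img)), c(20L, 12L))
  expect_error(loadUltrasound(f), "spacing")
  expect_error(loadUltrasound("no-such-file.png", 0.2), "not found")
})

test_that("16-bit input is min-max rescaled to 0-255 with a warning", {
  skip_if_not_installed("tiff")
  f <- withr::local_tempfile(fileext = ".tif")
  # 3-value toy image; rescale oracle: (v - min) / (max - min) * 255
  mat <- matrix(c(0L, 20000L, 40000L, 0L), 2, 2)
  tiff::writeTIFF(mat / 65535, f, bits.per.sample = 16L)
  expect_warning(img <- loadUltrasound(f, spacingOverride = 0.5), "rescal")
  expect_equal(sort(unique(as.vector(pixels(img)))), c(0, 128, 255))
})

test_that("minimal DICOM files load with pixel spacing from the header", {
  f <- withr::local_tempfile(fileext = ".dcm")
  mat <- matrix(0:249, 10, 25, byrow = TRUE)
  writeBin(makeDicomBytes(mat, spacing = c(0.3, 0.3)), f)
  img <- loadUltrasound(f)
  expect_equal(pixels(img), mat, ignore_attr = TRUE)
  expect_equal(pixelSpacing(img), 0.3)
  # 16-bit DICOM rescales with a warning
  f2 <- withr::local_tempfile(fileext = ".dcm")
  m2 <- matrix(c(0L, 500L, 1000L, 0L), 2, 2, byrow = TRUE)
  writeBin(makeDicomBytes(m2, spacing = c(0.1, 0.1), bits = 16), f2)
  expect_warning(img2 <- loadUltrasound(f2), "rescal")
  expect_equal(sort(unique(as.vector(pixels(img2)))), c(0, 128, 255))
})

test_that("rasterization follows the pixel-centre even-odd rule", {
  img <- methods::new("UltrasoundImage",
                      pixels = matrix(0, 10, 10), spacing = 1)
  rect <- regionAnnotation(rbind(c(1.5, 1.5), c(5.5, 1.5),
                                 c(5.5, 5.5), c(1.5, 5.5)))
  m <- maskMatrix(rasterizeAnnotation(rect, img))
  expect_equal(sum(m), 16)  # centres (2,2)..(5,5)
  expect_true(m[3, 3] && !m[7, 7])
  expect_error(regionAnnotation(rbind(c(0, 0), c(5, 5))), "3")
  oob <- regionAnnotation(rbind(c(-2, 0), c(5, 0), c(5, 5)))
  expect_error(rasterizeAnnotation(oob, img), "bounds")
})

test_that("rasterized area tracks the shoelace area and converges with scale", {
  tri <- rbind(c(5, 5), c(50, 10), c(20, 55))
  img <- methods::new("UltrasoundImage", pixels = matrix(0, 64, 64), spacing = 1)
  m <- maskMatrix(rasterizeAnnotation(regionAnnotation(tri), img))
  a <- oracleShoelace(tri)
  expect_lt(abs(sum(m) - a), 46)           # within one pixel-row of the bbox
  # doubled resolution: relative error shrinks
  img2 <- methods::new("UltrasoundImage", pixels = matrix(0, 128, 128), spacing = 0.5)
  m2 <- maskMatrix(rasterizeAnnotation(regionAnnotation(tri * 2), img2))
  relErr1 <- abs(sum(m) - a) / a
  relErr2 <- abs(sum(m2) / 4 - a) / a
  expect_lt(relErr2, relErr1 + 1e-9)
})

test_that("isolation excludes outside-mask pixels without zeroing statistics", {
  px <- matrix(runif(400, 0, 255), 20, 20)
  img <- methods::new("UltrasoundImage", pixels = px, spacing = 1)
  full <- methods::new("PancreasMask", mask = matrix(TRUE, 20, 20))
  iso <- isolatePancreas(img, full)
  expect_equal(mean(iso$values), mean(px))
  expect_equal(iso$n, 400)
  # constant patch inside noise: in-mask variance is 0
  px2 <- px; px2[5:8, 5:8] <- 120
  img2 <- methods::new("UltrasoundImage", pixels = px2, spacing = 1)
  patch <- matrix(FALSE, 20, 20); patch[5:8, 5:8] <- TRUE
  iso2 <- isolatePancreas(img2, methods::new("PancreasMask", mask = patch))
  expect_equal(var(iso2$values), 0)
  expect_equal(iso2$n, sum(patch))
  expect_equal(sum(iso2$display != 0), sum(patch))
  expect_error(isolatePancreas(img, methods::new("PancreasMask",
                                                 mask = matrix(TRUE, 5, 5))),
               "shapes")
})

test_that("region depth is the centroid row times spacing", {
  mk <- function(rows, nr = 200, spacing = 0.3) {
    m <- matrix(FALSE, nr, 8); m[rows + 1, 4] <- TRUE  # rows are 0-based
    list(mask = methods::new("PancreasMask", mask = m),
         img = methods::new("UltrasoundImage", pixels = matrix(0, nr, 8),
                            spacing = spacing))
  }
  x <- mk(100)
  expect_equal(regionDepth(x$mask, x$img), 3.0)
  y <- mk(c(50, 150), spacing = 0.2)
  expect_equal(regionDepth(y$mask, y$img), 2.0)
  # symmetric mask about row r has depth r * spacing
  z <- mk(c(80, 90, 100, 110, 120), spacing = 0.25)
  expect_equal(regionDepth(z$mask, z$img), 100 * 0.25 / 10)
})

test_that("region depth is invariant to horizontal and linear in vertical shifts", {
  base <- makeBlobFixture(7)
  m <- maskMatrix(base$mask)
  d0 <- regionDepth(base$mask, base$image)
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    rs <- max(1, 1 + dr):min(nrow(m), nrow(m) + dr)
    cs <- max(1, 1 + dc):min(ncol(m), ncol(m) + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  mh <- methods::new("PancreasMask", mask = shift(m, 0, 5))
  expect_equal(regionDepth(mh, base$image), d0)
  mv <- methods::new("PancreasMask", mask = shift(m, 10, 0))
  expect_equal(regionDepth(mv, base$image),
               d0 + 10 * pixelSpacing(base$image) / 10)
})

test_that("depth profiles retain all depths and report means and visibility", {
  df <- data.frame(
    patient = c("a", "a", "a", "b"),
    image = c("i1", "i2", "i1", "i3"),
    region = c("body", "body", "head", "body"),
    depth_cm = c(3, 5, 2.5, 4))
  dp <- depthProfile(df)
  expect_equal(nrow(dp$perRegion), 4)
  prog <- dp$progression
  expect_equal(prog$mean_depth_cm[prog$patient == "a" & prog$region == "body"], 4)
  vis <- dp$visibility
  expect_equal(vis$fraction[vis$region == "body"], 1)      # in all 3 images
  expect_equal(vis$fraction[vis$region == "head"], 1 / 3)
  expect_error(depthProfile(df[0, ]), "at least one")
})

test_that("annotations round-trip through JSON", {
  f <- withr::local_tempfile(fileext = ".json")
  ann <- regionAnnotation(rbind(c(1, 2), c(8, 2), c(5, 9)), region = "body")
  writeAnnotation(ann, f)
  back <- readAnnotation(f)
  expect_equal(back$vertices, ann$vertices, ignore_attr = TRUE)
  expect_equal(back$region, "body")
})
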