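# Fixtures built in code at test time.

# Minimal explicit-VR little-endian DICOM bytes for a single-frame
# monochrome image. Written byte-by-byte, independently of the package's
# reader.
makeDicomBytes <- function(mat, spacing = c(0.3, 0.3), bits = 8) {
  u16 <- function(x) as.raw(c(x %% 256, x %/% 256))
  u32 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                              (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
  tag <- function(grp, ele) c(u16(grp), u16(ele))
  elemShort <- function(grp, ele, vr, payload) {
    c(tag(grp, ele), charToRaw(vr), u16(length(payload)), payload)
  }
  elemLong <- function(grp, ele, vr, payload) {
    c(tag(grp, ele), charToRaw(vr), as.raw(c(0, 0)), u32(length(payload)),
      payload)
  }
  ds <- sprintf("%g\\%g", spacing[1], spacing[2])
  if (nchar(ds) %% 2 == 1) ds <- paste0(ds, " ")
  pix <- as.integer(t(mat))  # row-major
  payload <- if (bits == 8) as.raw(pix)
             else writeBin(pix, raw(), size = 2, endian = "little")
  c(as.raw(rep(0, 128)), charToRaw("DICM"),
    elemShort(0x0028, 0x0010, "US", u16(nrow(mat))),
    elemShort(0x0028, 0x0011, "US", u16(ncol(mat))),
    elemShort(0x0028, 0x0030, "DS", charToRaw(ds)),
    elemShort(0x0028, 0x0100, "US", u16(bits)),
    elemLong(0x7FE0, 0x0010, "OB", payload))
}

# A deterministic blob image + mask pair (small, for IO/feature tests).
makeBlobFixture <- function(seed = 42, shape = c(96, 96)) {
  generatePhantom(phantomSpec("non-DM", imageShape = shape,
                              pixelSpacing = 0.6, areaMean = 600,
                              areaSd = 50, depthMean = 2.6, depthSd = 0.2,
                              seed = seed))
}

# Effect-free phantom spec: both classes share every generating parameter.
nullPhantomSpec <- function(classLabel, seed) {
  phantomSpec(classLabel, imageShape = c(64, 64), pixelSpacing = 0.8,
              areaMean = 600, areaSd = 70, depthMean = 2.5, depthSd = 0.25,
              aspectMean = 1.6, aspectSd = 0.2, textureSmoothing = 1,
              coherentAmplitude = 0, seed = seed)
}

# A ThermalField with a spatially constant, time-constant temperature.
constantField <- function(tempC, minutes, nFrames = 11) {
  tms <- seq(0, minutes * 60, length.out = nFrames)
  nr <- 3L; nz <- 4L
  methods::new("ThermalField",
               frames = array(tempC, c(nr, nz, nFrames)), frameTimes = tms,
               onAxis = matrix(tempC, nz, nFrames), onAxisTimes = tms,
               r = seq(0, 0.002, length.out = nr),
               z = seq(0, 0.003, length.out = nz),
               maxT = matrix(tempC, nr, nz),
               tissueIndex = rep(1L, nz),
               layerNames = "pancreas",
               baseline = 37)
}
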