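# Image and annotation input/output, mask rasterization, depth descriptors.
#
# Coordinate convention: 0-based pixel indices; pixel (row r, col c) has its
# centre at (x = c, y = r); row 0 is the transducer/dermis face, so depth
# increases with the row index. Polygon vertices are [x, y] in these units.

#' Even-odd point-in-polygon mask over a pixel grid
#'
#' A pixel is foreground iff its centre lies inside the polygon under the
#' even-odd (ray crossing) rule.
#' @noRd
pointsInPolygonMask <- function(poly, nrow, ncol) {
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  # restrict the centre test to the polygon bounding box
  c0 <- max(0L, floor(min(px))); c1 <- min(ncol - 1L, ceiling(max(px)))
  r0 <- max(0L, floor(min(py))); r1 <- min(nrow - 1L, ceiling(max(py)))
  if (c1 < c0 || r1 < r0) return(matrix(FALSE, nrow, ncol))
  nrb <- r1 - r0 + 1L; ncb <- c1 - c0 + 1L
  xs <- rep(c0:c1, each = nrb)
  ys <- rep(r0:r1, times = ncb)
  inside <- logical(length(xs))
  j <- n
  for (i in seq_len(n)) {
    yi <- py[i]; yj <- py[j]; xi <- px[i]; xj <- px[j]
    crosses <- (yi > ys) != (yj > ys)
    if (any(crosses)) {
      xcut <- xi + (ys[crosses] - yi) * (xj - xi) / (yj - yi)
      flip <- xs[crosses] < xcut
      inside[crosses][flip] <- !inside[crosses][flip]
    }
    j <- i
  }
  out <- matrix(FALSE, nrow, ncol)
  out[(r0 + 1L):(r1 + 1L), (c0 + 1L):(c1 + 1L)] <- matrix(inside, nrb, ncb)
  out
}

#' Region annotation
#'
#' @param vertices n x 2 matrix of `[x, y]` polygon vertices in 0-based
#'   pixel coordinates (at least 3, simple polygon assumed).
#' @param region `"head"`, `"body"`, `"tail"` or `"whole"`.
#' @return list of class `"RegionAnnotation"`.
#' @export
regionAnnotation <- function(vertices, region = "whole") {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3 || ncol(vertices) != 2)
    stop("annotation needs at least 3 [x, y] vertices")
  if (!region %in% c("head", "body", "tail", "whole"))
    stop("region must be head/body/tail/whole")
  structure(list(vertices = vertices, region = region),
            class = "RegionAnnotation")
}

#' Read/write annotations as JSON
#'
#' JSON layout: `{"region": "...", "vertices": [[x, y], ...]}`.
#' @param path file path.
#' @export
readAnnotation <- function(path) {
  obj <- jsonlite::fromJSON(path)
  regionAnnotation(obj$vertices, obj$region %||% "whole")
}

#' @rdname readAnnotation
#' @param ann a [regionAnnotation()].
#' @export
writeAnnotation <- function(ann, path) {
  jsonlite::write_json(list(region = ann$region,
                            vertices = unname(ann$vertices)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rasterize a polygon annotation against an image grid
#'
#' @param ann a [regionAnnotation()].
#' @param image an [UltrasoundImage-class].
#' @return a [PancreasMask-class].
#' @export
rasterizeAnnotation <- function(ann, image) {
  stopifnot(inherits(ann, "RegionAnnotation"), is(image, "UltrasoundImage"))
  d <- dim(pixels(image))
  v <- ann$vertices
  if (any(v[, 1] < 0) || any(v[, 1] > d[2] - 1) ||
      any(v[, 2] < 0) || any(v[, 2] > d[1] - 1))
    stop("annotation vertices fall outside the image bounds")
  m <- pointsInPolygonMask(v, d[1], d[2])
  if (!any(m)) stop("rasterized annotation is empty")
  methods::new("PancreasMask", mask = m, regionLabel = ann$region)
}

# ---------------------------------------------------------------------------
# Loading

#' Minimal DICOM reader (single-frame, uncompressed, little endian)
#'
#' Parses explicit- or implicit-VR little-endian files, extracting Rows,
#' Columns, BitsAllocated, PixelSpacing and PixelData only. Sequences and
#' compressed transfer syntaxes are not supported.
#' @noRd
readDicomImage <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic)")
  pos <- 133L
  u16 <- function(at) as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
  u32 <- function(at) sum(as.numeric(raw[at + 0:3]) * 256^(0:3))
  fields <- list()
  expl2 <- c("AE","AS","AT","CS","DA","DS","DT","FL","FD","IS","LO","LT",
             "PN","SH","SL","SS","ST","TM","UI","UL","US")
  expl4 <- c("OB","OW","OF","SQ","UT","UN")
  nbytes <- length(raw)
  while (pos + 8L <= nbytes) {
    grp <- u16(pos); ele <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% expl2) {
      len <- u16(pos + 6L); dat <- pos + 8L
    } else if (vr %in% expl4) {
      len <- u32(pos + 8L); dat <- pos + 12L
    } else {  # implicit VR
      len <- u32(pos + 4L); dat <- pos + 8L
    }
    if (!is.finite(len) || len == 4294967295) stop("undefined-length DICOM element unsupported")
    tag <- sprintf("%04x,%04x", grp, ele)
    if (tag %in% c("0028,0010", "0028,0011", "0028,0100")) {
      fields[[tag]] <- u16(dat)
    } else if (tag == "0028,0030") {
      fields[[tag]] <- as.numeric(strsplit(trimws(rawToChar(raw[dat:(dat + len - 1L)])),
                                           "\\\\")[[1]])
    } else if (tag == "7fe0,0010") {
      fields[[tag]] <- raw[dat:(dat + len - 1L)]
      break
    }
    pos <- dat + len
  }
  need <- c("0028,0010", "0028,0011", "7fe0,0010")
  if (!all(need %in% names(fields))) stop("DICOM missing Rows/Columns/PixelData")
  rows <- fields[["0028,0010"]]; cols <- fields[["0028,0011"]]
  bits <- fields[["0028,0100"]] %||% 8L
  pix <- fields[["7fe0,0010"]]
  nper <- rows * cols
  if (length(pix) < nper * bits / 8) stop("truncated PixelData")
  vals <- if (bits == 8) as.integer(pix[seq_len(nper)])
          else readBin(pix, "integer", n = nper, size = 2, signed = FALSE,
                       endian = "little")
  if (length(pix) > nper * bits / 8)
    warning("multi-frame DICOM: using first frame only")
  # row-major pixel order
  mat <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
  list(pixels = mat, spacing = fields[["0028,0030"]], bits = bits)
}

#' Load a grayscale ultrasound image
#'
#' Supports 8/16-bit PNG and TIFF, and single-frame uncompressed DICOM.
#' Values outside the 8-bit range (16-bit sources) are min-max rescaled to
#' 0-255 with a warning. Pixel spacing comes from the DICOM PixelSpacing
#' tag when present; otherwise `spacingOverride` (mm/pixel) is required.
#'
#' @param path image file (.png, .tif/.tiff, .dcm).
#' @param spacingOverride mm per pixel; mandatory for PNG/TIFF.
#' @param patientId,classLabel optional metadata.
#' @return an [UltrasoundImage-class].
#' @export
loadUltrasound <- function(path, spacingOverride = NULL,
                           patientId = NA_character_, classLabel = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  spacing <- spacingOverride
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                        c(1, 2), mean)
    mat <- round(a * 255)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to read TIFF images")
    a <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(a)) == 3) a <- apply(a, c(1, 2), mean)
    mat <- a
  } else if (ext %in% c("dcm", "dicom", "")) {
    d <- readDicomImage(path)
    mat <- d$pixels
    if (!is.null(d$spacing) && is.null(spacing)) spacing <- mean(d$spacing)
  } else stop("unsupported image format: .", ext)
  if (max(mat) > 255 || min(mat) < 0) {
    warning("rescaling intensities beyond the 8-bit range to 0-255")
    rng <- range(mat)
    mat <- if (diff(rng) == 0) mat * 0 else round(255 * (mat - rng[1]) / diff(rng))
  }
  if (is.null(spacing))
    stop("pixel spacing unavailable: supply spacingOverride (mm/pixel)")
  methods::new("UltrasoundImage", pixels = mat, spacing = spacing,
               patientId = patientId, classLabel = classLabel)
}

#' Read a 0/255 PNG mask
#'
#' @param path PNG file.
#' @param region region label for the mask.
#' @return a [PancreasMask-class].
#' @export
readMaskPNG <- function(path, region = "whole") {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  methods::new("PancreasMask", mask = a > 0.5, regionLabel = region)
}

# ---------------------------------------------------------------------------
# Masked statistics and depth

#' Isolate the pancreas region of an image
#'
#' Returns the in-mask pixel values (used for all statistics; pixels
#' outside the mask are excluded, not zeroed) plus a zero-filled copy for
#' visualization.
#'
#' @param image an [UltrasoundImage-class].
#' @param mask a [PancreasMask-class] of the same shape.
#' @return list with `values` (numeric vector of in-mask intensities),
#'   `n` (foreground count) and `display` (matrix with the outside zeroed).
#' @export
isolatePancreas <- function(image, mask) {
  px <- pixels(image); m <- maskMatrix(mask)
  if (!all(dim(px) == dim(m))) stop("image and mask shapes differ")
  if (!any(m)) stop("empty mask")
  disp <- px; disp[!m] <- 0
  list(values = px[m], n = sum(m), display = disp)
}

#' Depth of a masked region below the dermis, in cm
#'
#' Depth is the mean (centroid) 0-based row index of the foreground times
#' the pixel spacing, converted from mm to cm. Row 0 is the dermis face.
#'
#' @param mask a [PancreasMask-class].
#' @param image the matching [UltrasoundImage-class] (supplies spacing).
#' @return depth in cm.
#' @examples
#' # a single pixel on row 100 at 0.3 mm/px lies 3 cm deep
#' @export
regionDepth <- function(mask, image) {
  m <- maskMatrix(mask)
  if (!any(m)) stop("empty mask")
  rows0 <- row(m)[m] - 1
  mean(rows0) * pixelSpacing(image) / 10
}

#' Per-patient, per-region depth summaries for a cohort
#'
#' Input is a tidy table with one row per (patient, image, region) and a
#' depth column; typically assembled by calling [regionDepth()] over the
#' cohort annotations. All depths are retained; the per-(patient, region)
#' mean is reported separately for depth-progression displays, and the
#' fraction of images in which each region appears is summarised.
#'
#' @param depths data.frame with columns `patient`, `image`, `region`,
#'   `depth_cm`.
#' @return list with `perRegion` (all rows, unchanged), `progression`
#'   (patient x region mean depths) and `visibility` (per-region fraction
#'   of images containing the region).
#' @export
depthProfile <- function(depths) {
  stopifnot(all(c("patient", "image", "region", "depth_cm") %in% names(depths)))
  if (nrow(depths) < 1) stop("at least one annotated region required")
  prog <- stats::aggregate(depth_cm ~ patient + region, depths, mean)
  names(prog)[names(prog) == "depth_cm"] <- "mean_depth_cm"
  images <- unique(depths[, c("patient", "image")])
  nImg <- nrow(images)
  vis <- stats::aggregate(image ~ region, depths,
                          function(x) length(unique(x)))
  vis$fraction <- vis$image / nImg
  names(vis)[names(vis) == "image"] <- "n_images"
  list(perRegion = depths, progression = prog, visibility = vis)
}
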