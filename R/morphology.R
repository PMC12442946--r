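# Mask morphology: area, perimeter, centroid, aspect ratio, eccentricity.

#' Total polygonal length of the marching-squares iso-contour of a field
#'
#' Linear interpolation of the crossing points along cell edges; the two
#' ambiguous saddle cases are resolved by the cell-centre average.
#' Lengths are in pixel units.
#' @noRd
marchingSquaresLength <- function(f, level = 0.5) {
  nr <- nrow(f); nc <- ncol(f)
  if (nr < 2 || nc < 2) return(0)
  tl <- f[-nr, -nc]; tr <- f[-nr, -1]; br <- f[-1, -1]; bl <- f[-1, -nc]
  b <- (tl > level) * 8L + (tr > level) * 4L + (br > level) * 2L + (bl > level) * 1L
  # crossing offsets t in [0,1] along each cell edge (NA when no crossing)
  tTop <- (level - tl) / (tr - tl)
  tRight <- (level - tr) / (br - tr)
  tBottom <- (level - bl) / (br - bl)
  tLeft <- (level - tl) / (bl - tl)
  J <- col(tl) - 1; I <- row(tl) - 1   # cell origin (0-based node coords)
  # crossing point coordinates (x, y) per edge
  ex <- list(top = J + tTop, right = J + 1, bottom = J + tBottom, left = J)
  ey <- list(top = I, right = I + tRight, bottom = I + 1, left = I + tLeft)
  segLen <- function(cells, e1, e2) {
    if (!any(cells)) return(0)
    dx <- ex[[e1]][cells] - ex[[e2]][cells]
    dy <- ey[[e1]][cells] - ey[[e2]][cells]
    sum(sqrt(dx^2 + dy^2))
  }
  single <- list(`1` = c("left", "bottom"), `2` = c("bottom", "right"),
                 `4` = c("top", "right"), `8` = c("top", "left"),
                 `3` = c("left", "right"), `6` = c("top", "bottom"),
                 `12` = c("left", "right"), `9` = c("top", "bottom"),
                 `7` = c("top", "left"), `11` = c("top", "right"),
                 `13` = c("bottom", "right"), `14` = c("left", "bottom"))
  total <- 0
  for (cs in names(single)) {
    cells <- b == as.integer(cs)
    total <- total + segLen(cells, single[[cs]][1], single[[cs]][2])
  }
  centre <- (tl + tr + br + bl) / 4
  for (cs in c(5L, 10L)) {
    cells <- b == cs
    if (!any(cells)) next
    inside <- centre > level
    a1 <- cells & if (cs == 5L) inside else !inside     # top-left + bottom-right
    a2 <- cells & !(if (cs == 5L) inside else !inside)  # top-right + left-bottom
    total <- total + segLen(a1, "top", "left") + segLen(a1, "bottom", "right") +
      segLen(a2, "top", "right") + segLen(a2, "left", "bottom")
  }
  total
}

#' Morphological features of a pancreas mask
#'
#' Area is the foreground pixel count times spacing^2 (mm^2). The perimeter
#' is the polygonal length of the marching-squares 0.5-level contour of the
#' Gaussian-smoothed (sigma = 1 px) indicator, times spacing (mm); the
#' smoothing gives sub-pixel crossings so digitised smooth shapes recover
#' their true boundary length closely. Centroids are in cm from the
#' image origin (x = columns, y = rows/depth). Aspect ratio is the
#' bounding-box width/height; eccentricity comes from the second central
#' moments of the foreground.
#'
#' @param mask a [PancreasMask-class] (or logical matrix).
#' @param spacing mm per pixel.
#' @return named numeric: `area`, `perimeter`, `centroid_x`, `centroid_y`,
#'   `aspect_ratio`, `eccentricity`, plus pixel-unit centroids as
#'   attributes `centroid_col_px`, `centroid_row_px`.
#' @export
morphologyFeatures <- function(mask, spacing) {
  m <- if (is(mask, "PancreasMask")) maskMatrix(mask) else mask
  if (!any(m)) stop("empty mask")
  if (spacing <= 0) stop("spacing must be > 0")
  rows0 <- row(m)[m] - 1; cols0 <- col(m)[m] - 1
  n <- length(rows0)
  area <- n * spacing^2
  perim <- marchingSquaresLength(sepBlur(m * 1, 1), 0.5) * spacing
  cx <- mean(cols0); cy <- mean(rows0)
  w <- diff(range(cols0)) + 1; h <- diff(range(rows0)) + 1
  mu20 <- mean((cols0 - cx)^2); mu02 <- mean((rows0 - cy)^2)
  mu11 <- mean((cols0 - cx) * (rows0 - cy))
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  lmax <- (mu20 + mu02 + common) / 2
  lmin <- (mu20 + mu02 - common) / 2
  ecc <- if (lmax <= 0) 0 else sqrt(pmax(0, 1 - lmin / lmax))
  out <- c(area = area, perimeter = perim,
           centroid_x = cx * spacing / 10, centroid_y = cy * spacing / 10,
           aspect_ratio = w / h, eccentricity = ecc)
  attr(out, "centroid_col_px") <- cx
  attr(out, "centroid_row_px") <- cy
  out
}
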