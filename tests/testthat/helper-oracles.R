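# Independent brute-force oracles. These deliberately share no code with
# the package implementations: scalar loops and textbook formulas only.

# --- masked GLCM by explicit pair enumeration -------------------------------
oracleGLCM <- function(img, mask, levels = 32, distance = 1,
                       angles = c(0, 45, 90, 135)) {
  v <- img[mask]
  lo <- min(v); hi <- max(v)
  if (hi == lo) return(NULL)
  L <- levels
  q <- matrix(NA_integer_, nrow(img), ncol(img))
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    if (mask[r, c]) {
      b <- floor((img[r, c] - lo) / (hi - lo) * L) + 1
      q[r, c] <- min(L, b)
    }
  }
  offs <- list(`0` = c(0, distance), `45` = c(-distance, distance),
               `90` = c(-distance, 0), `135` = c(-distance, -distance))
  C <- matrix(0, L, L)
  for (a in as.character(angles)) {
    o <- offs[[a]]
    for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
      r2 <- r + o[1]; c2 <- c + o[2]
      if (r2 >= 1 && r2 <= nrow(img) && c2 >= 1 && c2 <= ncol(img) &&
          !is.na(q[r, c]) && !is.na(q[r2, c2])) {
        C[q[r, c], q[r2, c2]] <- C[q[r, c], q[r2, c2]] + 1
      }
    }
  }
  C <- C + t(C)
  C / sum(C)
}

# --- the Haralick statistics by double loops --------------------------------
oracleHaralick <- function(P) {
  L <- nrow(P)
  lg2 <- function(x) if (x > 0) log2(x) else 0
  px <- rowSums(P); py <- colSums(P)
  mux <- 0; for (i in 1:L) mux <- mux + i * px[i]
  muy <- 0; for (j in 1:L) muy <- muy + j * py[j]
  sx <- sqrt(sum((1:L - mux)^2 * px)); sy <- sqrt(sum((1:L - muy)^2 * py))
  asm <- 0; con <- 0; cor <- 0; varr <- 0; idm <- 0; ent <- 0; hxy1 <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    asm <- asm + p^2
    con <- con + (i - j)^2 * p
    cor <- cor + i * j * p
    varr <- varr + (i - mux)^2 * p
    idm <- idm + p / (1 + (i - j)^2)
    ent <- ent - p * lg2(p)
    hxy1 <- hxy1 - p * lg2(px[i] * py[j])
  }
  cor <- if (sx * sy == 0) 1 else (cor - mux * muy) / (sx * sy)
  psum <- numeric(2 * L); pdiff <- numeric(L)
  for (i in 1:L) for (j in 1:L) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + P[i, j]
  }
  sumavg <- 0; for (k in 2:(2 * L)) sumavg <- sumavg + k * psum[k]
  sumvar <- 0; for (k in 2:(2 * L)) sumvar <- sumvar + (k - sumavg)^2 * psum[k]
  sument <- 0; for (k in 2:(2 * L)) sument <- sument - psum[k] * lg2(psum[k])
  dmean <- 0; for (k in 0:(L - 1)) dmean <- dmean + k * pdiff[k + 1]
  dvar <- 0; for (k in 0:(L - 1)) dvar <- dvar + (k - dmean)^2 * pdiff[k + 1]
  dent <- 0; for (k in 0:(L - 1)) dent <- dent - pdiff[k + 1] * lg2(pdiff[k + 1])
  hx <- 0; for (i in 1:L) hx <- hx - px[i] * lg2(px[i])
  hy <- 0; for (j in 1:L) hy <- hy - py[j] * lg2(py[j])
  hxy2 <- 0
  for (i in 1:L) for (j in 1:L)
    hxy2 <- hxy2 - px[i] * py[j] * lg2(px[i] * py[j])
  imc1 <- if (max(hx, hy) == 0) 0 else (ent - hxy1) / max(hx, hy)
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))
  c(haralick_asm = asm, haralick_contrast = con, haralick_correlation = cor,
    haralick_variance = varr, haralick_idm = idm, haralick_sum_average = sumavg,
    haralick_sum_variance = sumvar, haralick_sum_entropy = sument,
    haralick_entropy = ent, haralick_difference_variance = dvar,
    haralick_difference_entropy = dent, haralick_imc1 = imc1,
    haralick_imc2 = imc2)
}

# --- per-pixel rotation-invariant uniform LBP -------------------------------
oracleLBP <- function(img, mask, radius = 1, points = 8) {
  nr <- nrow(img); nc <- ncol(img)
  R <- ceiling(radius)
  hist <- numeric(points + 2)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    ok <- TRUE
    for (dr in -R:R) for (dc in -R:R) {
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc || !mask[rr, cc]) ok <- FALSE
    }
    if (!ok) next
    s <- logical(points)
    for (p in 0:(points - 1)) {
      a <- 2 * pi * p / points
      ry <- r - radius * sin(a); cx <- c + radius * cos(a)
      r0 <- min(floor(ry), nr - 1); c0 <- min(floor(cx), nc - 1)
      fr <- ry - r0; fc <- cx - c0
      g <- img[r0, c0] * (1 - fr) * (1 - fc) + img[r0 + 1, c0] * fr * (1 - fc) +
        img[r0, c0 + 1] * (1 - fr) * fc + img[r0 + 1, c0 + 1] * fr * fc
      s[p + 1] <- g >= img[r, c] - 1e-7
    }
    tr <- 0
    for (p in 1:points) tr <- tr + (s[p] != s[p %% points + 1])
    code <- if (tr <= 2) sum(s) else points + 1
    hist[code + 1] <- hist[code + 1] + 1
  }
  if (sum(hist) == 0) return(NULL)
  hist / sum(hist)
}

# --- AUC by all-pairs counting ----------------------------------------------
oracleAUC <- function(values, labels01) {
  pos <- values[labels01 == 1]; neg <- values[labels01 == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# --- polygon area by the shoelace formula -----------------------------------
oracleShoelace <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) {
    j <- i %% n + 1
    s <- s + x[i] * y[j] - x[j] * y[i]
  }
  abs(s) / 2
}

# --- on-axis gain of a focused bowl by Rayleigh-integral quadrature ---------
oracleBowlGain <- function(z_m, focus_m, radius_m, k, nTheta = 40000) {
  thetaA <- asin(radius_m / focus_m)
  th <- (seq_len(nTheta) - 0.5) * thetaA / nTheta
  dth <- thetaA / nTheta
  zs <- focus_m * (1 - cos(th))
  rs <- focus_m * sin(th)
  R <- sqrt(rs^2 + (z_m - zs)^2)
  integ <- sum(exp(1i * k * R) / R * focus_m^2 * sin(th)) * dth
  (k / (2 * pi)) * abs(2 * pi * integ)
}

# --- Spearman rho with midranks, by the definition --------------------------
oracleSpearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}
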