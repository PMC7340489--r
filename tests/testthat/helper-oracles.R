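# Independent brute-force oracles, written from the definition formulas
# with naive loops. They deliberately share no code with the package
# internals they check.

oracle_moments <- function(values) {
  n <- length(values[[1]])
  out <- list(mean = numeric(0), variance = numeric(0),
              skewness = numeric(0))
  for (nm in names(values)) {
    x <- values[[nm]]
    mu <- sum(x) / n
    m2 <- sum((x - mu)^2) / n
    m3 <- sum((x - mu)^3) / n
    out$mean[nm] <- mu
    out$variance[nm] <- m2
    out$skewness[nm] <- if (m2 > 0) m3 / m2^(3 / 2) else NA_real_
  }
  k <- length(values)
  covm <- corrm <- matrix(NA_real_, k, k,
                          dimnames = list(names(values), names(values)))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    xa <- values[[a]]; xb <- values[[b]]
    cv <- sum((xa - mean(xa)) * (xb - mean(xb))) / n
    covm[a, b] <- cv
    sa <- sqrt(out$variance[[a]]); sb <- sqrt(out$variance[[b]])
    corrm[a, b] <- if (sa > 0 && sb > 0) cv / (sa * sb) else NA_real_
  }
  out$cov <- covm; out$corr <- corrm
  out
}

# Pairwise co-occurrence by explicit enumeration of every pixel pair.
oracle_glcm <- function(levels, G, angle_deg, d = 1L, symmetric = TRUE) {
  off <- switch(as.character(angle_deg),
                "0" = c(0L, d), "45" = c(-d, d),
                "90" = c(-d, 0L), "135" = c(-d, -d))
  counts <- matrix(0, G, G)
  nr <- nrow(levels); nc <- ncol(levels)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + off[1]; c2 <- c + off[2]
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    a <- levels[r, c]; b <- levels[r2, c2]
    if (is.na(a) || is.na(b)) next
    counts[a + 1L, b + 1L] <- counts[a + 1L, b + 1L] + 1
    if (symmetric) counts[b + 1L, a + 1L] <- counts[b + 1L, a + 1L] + 1
  }
  counts / sum(counts)
}

# All descriptors by definition sums with explicit double loops.
oracle_haralick <- function(P) {
  G <- nrow(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum((1:G) * px); muy <- sum((1:G) * py)
  sx <- sqrt(sum(((1:G) - mux)^2 * px))
  sy <- sqrt(sum(((1:G) - muy)^2 * py))
  psum <- rep(0, 2 * G); pdif <- rep(0, G)
  f1 <- f2 <- f3n <- f4 <- f5 <- f9 <- 0
  for (i in 1:G) for (j in 1:G) {
    p <- P[i, j]
    f1 <- f1 + p^2
    f2 <- f2 + (i - j)^2 * p
    f3n <- f3n + i * j * p
    f4 <- f4 + (i - mux)^2 * p
    f5 <- f5 + p / (1 + (i - j)^2)
    if (p > 0) f9 <- f9 - p * log2(p)
    psum[i + j] <- psum[i + j] + p
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p
  }
  f3 <- if (sx > 0 && sy > 0) (f3n - mux * muy) / (sx * sy) else NA_real_
  f6 <- sum((2:(2 * G)) * psum[2:(2 * G)])
  f7 <- sum(((2:(2 * G)) - f6)^2 * psum[2:(2 * G)])
  f8 <- -sum(psum[psum > 0] * log2(psum[psum > 0]))
  mud <- sum((0:(G - 1)) * pdif)
  f10 <- sum(((0:(G - 1)) - mud)^2 * pdif)
  f11 <- -sum(pdif[pdif > 0] * log2(pdif[pdif > 0]))
  hxy1 <- 0; hxy_n <- 0; hxy2_n <- 0
  for (i in 1:G) for (j in 1:G) {
    q <- px[i] * py[j]
    if (q > 0) {
      if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * log2(q)
      hxy2_n <- hxy2_n - q * log(q)
    }
    if (P[i, j] > 0) hxy_n <- hxy_n - P[i, j] * log(P[i, j])
  }
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  f12 <- if (max(hx, hy) > 0) (f9 - hxy1) / max(hx, hy) else NA_real_
  f13 <- sqrt(max(1 - exp(-2 * (hxy2_n - hxy_n)), 0))
  nz <- which(px > 0 & py > 0)
  f14 <- NA_real_
  if (length(nz) >= 2) {
    Q <- matrix(0, length(nz), length(nz))
    for (a in seq_along(nz)) for (b in seq_along(nz)) {
      s <- 0
      for (k in nz)
        s <- s + P[nz[a], k] * P[nz[b], k] / (px[nz[a]] * py[k])
      Q[a, b] <- s
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    f14 <- sqrt(max(ev[2], 0))
  }
  list(f_asm = f1, f_contrast = f2, f_correlation = f3, f_variance = f4,
       f_homogeneity = f5, f_sum_avg = f6, f_sum_var = f7,
       f_sum_entropy = f8, f_entropy = f9, f_diff_var = f10,
       f_diff_entropy = f11, f_imc = f12, f_max_corr_coeff = f14,
       f_imc2 = f13)
}

# Vegetation indices re-derived expression by expression.
oracle_vi <- function(bv, L = 0.5, gamma = 1) {
  nir <- bv$nir1; red <- bv$red; blue <- bv$blue; green <- bv$green
  dv <- function(a, b) ifelse(b == 0, NA_real_, a / b)
  out <- list(
    ndvi = dv(nir - red, nir + red),
    gndvi = dv(nir - green, nir + green),
    evi = dv(2.5 * (nir - red), nir + 6 * red - 7.5 * blue + 1),
    sr = dv(nir, red),
    savi = dv((1 + L) * (nir - red), nir + red + L),
    msavi2 = (2 * nir + 1 - sqrt((2 * nir + 1)^2 - 8 * (nir - red))) / 2)
  rrb <- red - gamma * (blue - red)
  out$sarvi <- dv((1 + L) * (nir - rrb), nir + rrb + L)
  if (!is.null(bv$rededge)) {
    re <- bv$rededge
    out$tcari <- 3 * ((re - red) - 0.2 * (re - green) * dv(re, red))
  }
  if (!is.null(bv$nir2))
    out$ndvi_nir2 <- dv(bv$nir2 - red, bv$nir2 + red)
  out
}

oracle_residual_stats <- function(sp, cp) {
  dx <- sp[, 1] - cp[, 1]; dy <- sp[, 2] - cp[, 2]
  list(mean_abs_dx = mean(abs(dx)), sd_abs_dx = sd(abs(dx)),
       mean_abs_dy = mean(abs(dy)), sd_abs_dy = sd(abs(dy)),
       min_dx = min(dx), max_dx = max(dx),
       min_dy = min(dy), max_dy = max(dy),
       rmse_x = sqrt(mean(dx^2)), rmse_y = sqrt(mean(dy^2)))
}

# convenience: a tiny valid 4-band scene from band value matrices
tiny_scene <- function(nir, gsd = 2, origin = c(0, 1000), id = "T") {
  d <- dim(nir)
  const <- function(v) matrix(v, d[1], d[2])
  scene(list(blue = const(0.1), green = const(0.12), red = const(0.15),
             nir1 = nir),
        geotransform = c(origin, gsd, gsd), crs_id = "EPSG:32630",
        scene_id = id)
}

test_meta <- function(id = "S1", sun = 55, time = "2015-05-18T10:46:00Z",
                      cloud_pct = 0, offnadir = 0, sat_az = 0) {
  scene_metadata(id, time, sun_elevation_deg = sun,
                 sat_offnadir_deg = offnadir, sat_azimuth_deg = sat_az,
                 cloud_cover_pct = cloud_pct)
}
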