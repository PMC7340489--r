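# Grey-level co-occurrence texture over irregular field supports.
#
# Quantization stretches each field's own min-max range linearly into G
# levels (texture is a within-field property; a global stretch would
# couple fields). Co-occurrence uses displacement distance d (default 1
# pixel) at angles 0/45/90/135 degrees, symmetric by default, and only
# pixel pairs with both members inside the field contribute. Entropic
# descriptors are reported in bits (log base 2).

#' Co-occurrence specification
#'
#' @param grey_levels number of quantization levels (>= 2; the field
#'   workflow uses 64 and 256).
#' @param angle_deg displacement angle: 0, 45, 90 or 135 degrees (0 =
#'   east/west along rows of constant y, 90 = north/south).
#' @param distance_px displacement length in pixels (>= 1).
#' @param symmetric count each pair in both directions.
#' @return a `ps_glcm_spec`.
#' @export
glcm_spec <- function(grey_levels = 64L, angle_deg = 0L,
                      distance_px = 1L, symmetric = TRUE) {
  if (grey_levels < 2L) stop("grey_levels must be >= 2")
  if (!angle_deg %in% c(0L, 45L, 90L, 135L))
    stop("angle_deg must be one of 0, 45, 90, 135")
  if (distance_px < 1L) stop("distance_px must be >= 1")
  structure(list(grey_levels = as.integer(grey_levels),
                 angle_deg = as.integer(angle_deg),
                 distance_px = as.integer(distance_px),
                 symmetric = isTRUE(symmetric)),
            class = "ps_glcm_spec")
}

#' Quantize field values to grey levels
#'
#' Linear binning of the value range [lo, hi] into G levels 0..G-1; a
#' constant field maps to level 0. NA stays NA (outside the field).
#'
#' @param values numeric matrix (NA outside the field support).
#' @param G number of levels.
#' @param lo,hi stretch range; defaults to the field's own min/max.
#' @return integer matrix of levels in 0..G-1.
#' @export
quantize_levels <- function(values, G, lo = NULL, hi = NULL) {
  v <- values
  fin <- !is.na(v)
  if (!any(fin)) return(matrix(NA_integer_, nrow(v), ncol(v)))
  if (is.null(lo)) lo <- min(v[fin])
  if (is.null(hi)) hi <- max(v[fin])
  out <- matrix(NA_integer_, nrow(v), ncol(v))
  if (hi <= lo) {
    out[fin] <- 0L
    return(out)
  }
  lv <- floor((v[fin] - lo) / (hi - lo) * G)
  lv[lv > G - 1L] <- G - 1L
  lv[lv < 0L] <- 0L
  out[fin] <- as.integer(lv)
  out
}

glcm_offset <- function(spec) {
  d <- spec$distance_px
  switch(as.character(spec$angle_deg),
         "0" = c(0L, d),     # (drow, dcol): east
         "45" = c(-d, d),    # north-east
         "90" = c(-d, 0L),   # north
         "135" = c(-d, -d))  # north-west
}

#' Grey-level co-occurrence matrix over an irregular support
#'
#' Counts ordered level pairs at the spec's displacement among pixel pairs
#' whose two members both carry a level (are inside the field),
#' symmetrizes if requested, and normalizes to sum 1.
#'
#' @param levels integer matrix of quantized levels 0..G-1, NA outside the
#'   field.
#' @param spec a [glcm_spec()].
#' @return G x G matrix P with `sum(P) == 1`.
#' @export
glcm <- function(levels, spec) {
  stopifnot(inherits(spec, "ps_glcm_spec"))
  G <- spec$grey_levels
  if (any(levels >= G, na.rm = TRUE) || any(levels < 0, na.rm = TRUE))
    stop("levels exceed the quantization range")
  off <- glcm_offset(spec)
  nr <- nrow(levels); nc <- ncol(levels)
  r1 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  c1 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  if (length(r1) == 0L || length(c1) == 0L)
    stop("degenerate field: no co-occurring pixel pairs")
  a <- levels[r1, c1, drop = FALSE]
  b <- levels[r1 + off[1], c1 + off[2], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("degenerate field: no co-occurring pixel pairs")
  counts <- matrix(tabulate(a[ok] * G + b[ok] + 1L, nbins = G * G),
                   G, G, byrow = TRUE)
  if (spec$symmetric) counts <- counts + t(counts)
  counts / sum(counts)
}

#' Haralick descriptors of a normalized co-occurrence matrix
#'
#' The thirteen texture descriptors: angular second moment, contrast,
#' correlation, variance, local homogeneity (inverse difference moment),
#' sum average, sum variance, sum entropy, entropy, difference variance,
#' difference entropy, the first information measure of correlation
#' (`f_imc`), and the maximal correlation coefficient (square root of the
#' second-largest eigenvalue of the level-transition matrix Q). The
#' second information measure is additionally returned as `f_imc2`.
#' Entropies are in bits; sum variance is centred on the sum average;
#' variance is centred on the marginal mean. NA marks numerically
#' undefined descriptors.
#'
#' @param P square numeric matrix, normalized to sum 1.
#' @return named list of 14 numeric values.
#' @export
haralick <- function(P) {
  if (!is.matrix(P) || nrow(P) != ncol(P))
    stop("P must be a square matrix")
  if (abs(sum(P) - 1) > 1e-8 || any(P < 0))
    stop("P must be normalized to sum 1")
  G <- nrow(P)
  i <- matrix(seq_len(G), G, G)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(G) * px); muy <- sum(seq_len(G) * py)
  sx <- sqrt(sum((seq_len(G) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(G) - muy)^2 * py))
  log2z <- function(v) ifelse(v > 0, log2(v), 0)
  logz <- function(v) ifelse(v > 0, log(v), 0)

  # sum and difference distributions over i+j and |i-j|
  psum <- vapply(2:(2 * G), function(k) sum(P[i + j == k]), 0)
  kdif <- 0:(G - 1)
  pdif <- vapply(kdif, function(k) sum(P[abs(i - j) == k]), 0)

  f1 <- sum(P^2)
  f2 <- sum(kdif^2 * pdif)
  f3 <- if (sx > 0 && sy > 0)
    (sum(i * j * P) - mux * muy) / (sx * sy) else NA_real_
  f4 <- sum((i - mux)^2 * P)
  f5 <- sum(P / (1 + (i - j)^2))
  ks <- 2:(2 * G)
  f6 <- sum(ks * psum)
  f7 <- sum((ks - f6)^2 * psum)
  f8 <- -sum(psum * log2z(psum))
  f9 <- -sum(P * log2z(P))
  mud <- sum(kdif * pdif)
  f10 <- sum((kdif - mud)^2 * pdif)
  f11 <- -sum(pdif * log2z(pdif))

  pxy <- outer(px, py)
  hxy1 <- -sum(P * log2z(pxy))
  hx <- -sum(px * log2z(px)); hy <- -sum(py * log2z(py))
  denom <- max(hx, hy)
  f12 <- if (denom > 0) (f9 - hxy1) / denom else NA_real_
  # IMC2 needs natural-log entropies for its exponential form
  hxy_n <- -sum(P * logz(P))
  hxy2_n <- -sum(pxy * logz(pxy))
  arg <- 1 - exp(-2 * (hxy2_n - hxy_n))
  f13 <- if (is.finite(arg) && arg >= 0) sqrt(arg) else NA_real_

  f14 <- tryCatch({
    nz <- which(px > 0 & py > 0)
    if (length(nz) < 2L) NA_real_ else {
      Pq <- P[nz, nz, drop = FALSE]
      Q <- (Pq / px[nz]) %*% t(Pq / matrix(py[nz], length(nz),
                                           length(nz), byrow = TRUE))
      ev <- sort(Re(eigen(Q, only.values = TRUE)$values),
                 decreasing = TRUE)
      if (ev[2] < -1e-10) NA_real_ else sqrt(max(ev[2], 0))
    }
  }, error = function(e) NA_real_)

  list(f_asm = f1, f_contrast = f2, f_correlation = f3, f_variance = f4,
       f_homogeneity = f5, f_sum_avg = f6, f_sum_var = f7,
       f_sum_entropy = f8, f_entropy = f9, f_diff_var = f10,
       f_diff_entropy = f11, f_imc = f12, f_max_corr_coeff = f14,
       f_imc2 = f13)
}

#' Per-field texture records on a single band
#'
#' Quantizes the field's used pixels on the designated band (per-field
#' min-max stretch) and produces one record per grey-level setting (64,
#' 256) and angle (0, 45, 90, 135): eight records per field. Fields with
#' fewer than 4 usable pixels or no co-occurring pairs get records with NA
#' descriptors.
#'
#' @param scene a `ps_scene`.
#' @param poly a (buffered) `ps_field` or `NULL`.
#' @param mask optional `ps_mask`.
#' @param band_role band to measure texture on (panchromatic when
#'   available).
#' @param distance_px co-occurrence displacement length.
#' @return list of flat texture records.
#' @export
field_texture <- function(scene, poly, mask = NULL, band_role = "pan",
                          distance_px = 1L) {
  band <- scene_band(scene, band_role)
  px <- field_pixels(scene, poly, mask)
  vals <- matrix(NA_real_, nrow(band), ncol(band))
  vals[px$used] <- band[px$used]
  field_id <- if (is.null(poly)) NA_character_ else poly$field_id
  na_rec <- as.list(stats::setNames(rep(NA_real_, 14),
                                    c("f_asm", "f_contrast",
                                      "f_correlation", "f_variance",
                                      "f_homogeneity", "f_sum_avg",
                                      "f_sum_var", "f_sum_entropy",
                                      "f_entropy", "f_diff_var",
                                      "f_diff_entropy", "f_imc",
                                      "f_max_corr_coeff", "f_imc2")))
  recs <- list()
  for (G in c(64L, 256L)) {
    lv <- quantize_levels(vals, G)
    for (ang in c(0L, 45L, 90L, 135L)) {
      spec <- glcm_spec(G, ang, distance_px)
      desc <- if (length(px$used) < 4L) na_rec else
        tryCatch(haralick(glcm(lv, spec)), error = function(e) na_rec)
      recs[[length(recs) + 1L]] <-
        c(list(scene_id = scene$scene_id, field_id = field_id,
               grey_levels = G, angle_deg = ang), desc)
    }
  }
  recs
}
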