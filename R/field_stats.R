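# Object-based per-field statistics: negative boundary buffer, masked
# pixel selection, spectral moments with band correlation/covariance, and
# nine vegetation indices summarised per field.
#
# Conventions: population (n-denominator) variance, covariance and
# moment-ratio skewness g1 = m3 / m2^(3/2); undefined statistics are NA
# (rendered as empty CSV cells); pixel membership is centre-in-polygon.

#' Shrink a field polygon by an inward Euclidean buffer
#'
#' The conventional 2 m negative buffer discards potentially mixed pixels
#' along the field boundary. Supported for convex rings (fields are
#' rectangles or convex polygons here); a polygon that collapses under the
#' buffer comes back empty.
#'
#' @param poly a `ps_field`.
#' @param buffer_m inward offset in metres (>= 0).
#' @return a `ps_field` with the shrunken ring, or `NULL` when the polygon
#'   collapses.
#' @export
buffer_field <- function(poly, buffer_m = 2) {
  stopifnot(inherits(poly, "ps_field"))
  if (buffer_m < 0) stop("buffer_m must be >= 0")
  if (buffer_m == 0) return(poly)
  ring <- inward_offset_convex(poly$ring, buffer_m)
  if (nrow(ring) == 0L) return(NULL)
  field_polygon(poly$field_id, poly$crop, ring)
}

#' Select the pixels of a field
#'
#' `total` = linear indices of pixels whose centres fall inside the
#' polygon and are not nodata; `used` = `total` minus masked pixels.
#'
#' @param scene a `ps_scene`.
#' @param poly a (typically already buffered) `ps_field`, or `NULL`.
#' @param mask optional `ps_mask` aligned to the scene.
#' @return `list(total, used)` of linear (column-major) pixel indices.
#' @export
field_pixels <- function(scene, poly, mask = NULL) {
  d <- scene_dim(scene)
  if (is.null(poly))
    return(list(total = integer(0), used = integer(0)))
  if (!is.null(mask) && !all(dim(mask$grid) == d))
    stop("mask is not aligned to the scene grid")
  rows <- matrix(seq_len(d[1]), d[1], d[2])
  cols <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  ctr <- pixel_centre_xy(scene, as.vector(rows), as.vector(cols))
  inside <- points_in_polygon(ctr[, 1], ctr[, 2], poly$ring)
  nodata <- Reduce(`|`, lapply(scene$bands, is.na))
  total <- which(inside & !as.vector(nodata))
  used <- if (is.null(mask)) total else setdiff(total, which(mask$grid))
  list(total = total, used = used)
}

#' Spectral moments and band correlation/covariance
#'
#' Per band: mean, population variance (second central moment m2) and
#' moment-ratio skewness m3 / m2^(3/2); across bands: population
#' covariance and correlation matrices. With no pixels all statistics are
#' NA; a constant band has variance 0 and undefined (NA) skewness and
#' correlations.
#'
#' @param values named list of equal-length per-band reflectance vectors.
#' @return list `n`, `mean`, `variance`, `skewness` (named vectors),
#'   `cov`, `corr` (matrices).
#' @export
spectral_moments <- function(values) {
  lens <- unique(vapply(values, length, 0L))
  if (length(lens) != 1L) stop("bands have unequal pixel counts")
  n <- lens
  roles <- names(values)
  k <- length(values)
  if (n == 0L) {
    na <- stats::setNames(rep(NA_real_, k), roles)
    nam <- matrix(NA_real_, k, k, dimnames = list(roles, roles))
    return(list(n = 0L, mean = na, variance = na, skewness = na,
                cov = nam, corr = nam))
  }
  X <- do.call(cbind, values)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  m2 <- colMeans(Xc^2)
  m3 <- colMeans(Xc^3)
  skew <- ifelse(m2 > 0, m3 / m2^1.5, NA_real_)
  covm <- crossprod(Xc) / n
  s <- sqrt(m2)
  corrm <- covm / outer(s, s)
  corrm[!is.finite(corrm)] <- NA_real_
  dimnames(covm) <- dimnames(corrm) <- list(roles, roles)
  list(n = n, mean = stats::setNames(mu, roles),
       variance = stats::setNames(m2, roles),
       skewness = stats::setNames(as.numeric(skew), roles),
       cov = covm, corr = corrm)
}

#' Vegetation-index parameters
#'
#' @param L soil-adjustment constant for SAVI/SARVI (default 0.5).
#' @param gamma aerosol-resistance constant for SARVI (default 1).
#' @return a `ps_vi_params`.
#' @export
vi_params <- function(L = 0.5, gamma = 1) {
  if (L < 0) stop("L must be >= 0")
  structure(list(L = L, gamma = gamma), class = "ps_vi_params")
}

.VI_NAMES <- c("ndvi", "gndvi", "evi", "tcari", "sr", "sarvi", "savi",
               "msavi2", "ndvi_nir2")

# Roles each index needs; indices with absent roles are skipped.
.VI_NEEDS <- list(ndvi = c("nir1", "red"), gndvi = c("nir1", "green"),
                  evi = c("nir1", "red", "blue"),
                  tcari = c("rededge", "red", "green"),
                  sr = c("nir1", "red"),
                  sarvi = c("nir1", "red", "blue"),
                  savi = c("nir1", "red"), msavi2 = c("nir1", "red"),
                  ndvi_nir2 = c("nir2", "red"))

safe_div <- function(num, den) {
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Pixelwise vegetation indices
#'
#' Computes the nine indices (NDVI, green NDVI, EVI, TCARI, simple ratio
#' NIR/red, SARVI, SAVI, MSAVI2, and NDVI on the second NIR band) from
#' per-role reflectance vectors. Indices whose bands are absent (4-band
#' sensors lack red-edge and NIR2) are omitted from the result; division
#' by zero yields NA for that pixel.
#'
#' @param band_values named list of per-role reflectance vectors (roles
#'   among blue, green, red, rededge, nir1, nir2).
#' @param params a [vi_params()].
#' @return named list of per-pixel index vectors.
#' @export
vegetation_indices <- function(band_values, params = vi_params()) {
  stopifnot(inherits(params, "ps_vi_params"))
  have <- names(band_values)
  out <- list()
  g <- function(role) band_values[[role]]
  for (idx in .VI_NAMES) {
    if (!all(.VI_NEEDS[[idx]] %in% have)) next
    out[[idx]] <- switch(idx,
      ndvi = safe_div(g("nir1") - g("red"), g("nir1") + g("red")),
      gndvi = safe_div(g("nir1") - g("green"), g("nir1") + g("green")),
      evi = safe_div(2.5 * (g("nir1") - g("red")),
                     g("nir1") + 6 * g("red") - 7.5 * g("blue") + 1),
      tcari = 3 * ((g("rededge") - g("red")) -
                   0.2 * (g("rededge") - g("green")) *
                     safe_div(g("rededge"), g("red"))),
      sr = safe_div(g("nir1"), g("red")),
      sarvi = {
        rrb <- g("red") - params$gamma * (g("blue") - g("red"))
        safe_div((1 + params$L) * (g("nir1") - rrb),
                 g("nir1") + rrb + params$L)
      },
      savi = safe_div((1 + params$L) * (g("nir1") - g("red")),
                      g("nir1") + g("red") + params$L),
      msavi2 = {
        s <- (2 * g("nir1") + 1)^2 - 8 * (g("nir1") - g("red"))
        v <- (2 * g("nir1") + 1 - sqrt(pmax(s, 0))) / 2
        v[s < 0] <- NA_real_
        v
      },
      ndvi_nir2 = safe_div(g("nir2") - g("red"), g("nir2") + g("red")))
  }
  out
}

#' Per-field vegetation-index summary
#'
#' Mean and population standard deviation of each pixelwise index over the
#' used (unmasked) field pixels, ignoring pixels where the index is
#' undefined.
#'
#' @param scene a `ps_scene`.
#' @param poly a (buffered) `ps_field` or `NULL`.
#' @param mask optional `ps_mask`.
#' @param params a [vi_params()].
#' @return named list per index: `list(mean, sd)`.
#' @export
field_vi_summary <- function(scene, poly, mask = NULL,
                             params = vi_params()) {
  px <- field_pixels(scene, poly, mask)
  vals <- lapply(scene$bands, function(b) b[px$used])
  vi <- vegetation_indices(vals, params)
  lapply(vi, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(list(mean = NA_real_, sd = NA_real_))
    list(mean = mean(v), sd = sqrt(mean((v - mean(v))^2)))
  })
}
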