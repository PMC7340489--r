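# Tree-crown detection: scale-normalized Laplacian-of-Gaussian blob
# detection with automatic scale selection. A crown rendered as a Gaussian
# bump of scale s produces a response extremum at sigma = s, so the ladder
# position of the maximum recovers the crown scale; sub-voxel quadratic
# refinement in x, y and log(sigma) gives the reported centre and scale.

gaussian_kernel1d <- function(sigma_px, truncate = 4) {
  h <- max(1L, ceiling(truncate * sigma_px))
  x <- (-h):h
  k <- exp(-x^2 / (2 * sigma_px^2))
  k / sum(k)
}

# Dense 1-D convolution operator with mirror boundary, as an n x n matrix.
conv_matrix <- function(n, kernel) {
  h <- (length(kernel) - 1L) %/% 2L
  C <- matrix(0, n, n)
  for (o in (-h):h) {
    idx <- seq_len(n) + o
    idx[idx < 1L] <- 2L - idx[idx < 1L]
    idx[idx > n] <- 2L * n - idx[idx > n]
    C[cbind(seq_len(n), idx)] <- C[cbind(seq_len(n), idx)] + kernel[o + h + 1L]
  }
  C
}

gaussian_smooth <- function(mat, sigma_px) {
  k <- gaussian_kernel1d(sigma_px)
  Cr <- conv_matrix(nrow(mat), k)
  Cc <- conv_matrix(ncol(mat), k)
  Cr %*% mat %*% t(Cc)
}

# 5-point discrete Laplacian with replicated edges.
laplacian5 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- m[c(1L, seq_len(nr - 1L)), ]
  dn <- m[c(seq_len(nr - 1L) + 1L, nr), ]
  lf <- m[, c(1L, seq_len(nc - 1L))]
  rt <- m[, c(seq_len(nc - 1L) + 1L, nc)]
  up + dn + lf + rt - 4 * m
}

# Greyscale dilation over a 3x3 window (max-filter), replicated edges.
maxfilter3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  rowmax <- pmax(m[c(1L, seq_len(nr - 1L)), ], m,
                 m[c(seq_len(nr - 1L) + 1L, nr), ])
  pmax(rowmax[, c(1L, seq_len(nc - 1L))], rowmax,
       rowmax[, c(seq_len(nc - 1L) + 1L, nc)])
}

#' Blob-detector configuration
#'
#' @param sigma_min_m,sigma_max_m scale ladder bounds in metres
#'   (0 < min < max).
#' @param n_scales number of geometrically spaced ladder steps (>= 3).
#' @param response_threshold minimum scale-normalized response (a bright
#'   Gaussian bump of amplitude A peaks near A/2).
#' @param max_blobs keep at most this many strongest detections.
#' @return a `ps_detector_config` list.
#' @export
detector_config <- function(sigma_min_m = 2, sigma_max_m = 12,
                            n_scales = 12L, response_threshold = 0.02,
                            max_blobs = 2000L) {
  if (!(sigma_min_m > 0 && sigma_min_m < sigma_max_m))
    stop("need 0 < sigma_min_m < sigma_max_m")
  if (n_scales < 3L) stop("n_scales must be >= 3")
  structure(list(sigma_min_m = sigma_min_m, sigma_max_m = sigma_max_m,
                 n_scales = as.integer(n_scales),
                 response_threshold = response_threshold,
                 max_blobs = as.integer(max_blobs)),
            class = "ps_detector_config")
}

quad_offset <- function(fm, f0, fp) {
  den <- fp + fm - 2 * f0
  off <- ifelse(abs(den) < 1e-300, 0, (fm - fp) / (2 * den))
  pmin(pmax(off, -0.5), 0.5)
}

#' Detect tree-crown blobs with automatic scale selection
#'
#' Finds local maxima of the scale-normalized Laplacian-of-Gaussian
#' response over position and scale on one band (bright blobs on a darker
#' background, i.e. tree crowns on the NIR band). Centres and scales are
#' refined to sub-voxel precision and reported in map metres.
#'
#' @param scene a `ps_scene`.
#' @param band_role band to detect on (default `"nir1"`, where crown
#'   contrast is highest).
#' @param cfg a [detector_config()].
#' @return data frame with columns `x_m`, `y_m`, `sigma_m`, `response`,
#'   sorted by response descending and truncated to `cfg$max_blobs`.
#' @export
detect_blobs <- function(scene, band_role = "nir1",
                         cfg = detector_config()) {
  stopifnot(inherits(cfg, "ps_detector_config"))
  band <- scene_band(scene, band_role)
  empty <- data.frame(x_m = numeric(0), y_m = numeric(0),
                      sigma_m = numeric(0), response = numeric(0),
                      anisotropy = numeric(0))
  valid <- !is.na(band)
  if (!any(valid)) return(empty)
  band[!valid] <- stats::median(band[valid])
  px <- mean(scene$geotransform[3:4])
  ns <- cfg$n_scales
  sigmas_m <- cfg$sigma_min_m *
    (cfg$sigma_max_m / cfg$sigma_min_m)^((seq_len(ns) - 1) / (ns - 1))
  ratio <- (cfg$sigma_max_m / cfg$sigma_min_m)^(1 / (ns - 1))
  resp <- vector("list", ns)
  smoothed <- vector("list", ns)
  for (s in seq_len(ns)) {
    sp <- sigmas_m[s] / px
    smoothed[[s]] <- gaussian_smooth(band, sp)
    resp[[s]] <- -sp^2 * laplacian5(smoothed[[s]])
  }
  out <- empty
  nr <- nrow(band); nc <- ncol(band)
  for (s in 2:(ns - 1L)) {
    r0 <- resp[[s]]
    cand <- r0 > cfg$response_threshold &
      r0 >= maxfilter3(r0) &
      r0 > maxfilter3(resp[[s - 1L]]) &
      r0 > maxfilter3(resp[[s + 1L]])
    cand[c(1L, nr), ] <- FALSE
    cand[, c(1L, nc)] <- FALSE
    idx <- which(cand)
    if (!length(idx)) next
    rr <- (idx - 1L) %% nr + 1L
    cc <- (idx - 1L) %/% nr + 1L
    dr <- quad_offset(r0[cbind(rr - 1L, cc)], r0[idx], r0[cbind(rr + 1L, cc)])
    dc <- quad_offset(r0[cbind(rr, cc - 1L)], r0[idx], r0[cbind(rr, cc + 1L)])
    ds <- quad_offset(resp[[s - 1L]][idx], r0[idx], resp[[s + 1L]][idx])
    # curvature anisotropy trace^2/det of the Hessian of the smoothed
    # *image* at the peak: exactly 4 for an isotropic bell-shaped maximum,
    # larger for corners and edges, Inf for saddles. Cheap rejection of
    # non-crown structures before tie pointing / masking.
    L <- smoothed[[s]]
    dxx <- L[cbind(rr, cc - 1L)] + L[cbind(rr, cc + 1L)] - 2 * L[idx]
    dyy <- L[cbind(rr - 1L, cc)] + L[cbind(rr + 1L, cc)] - 2 * L[idx]
    dxy <- (L[cbind(rr + 1L, cc + 1L)] + L[cbind(rr - 1L, cc - 1L)] -
            L[cbind(rr + 1L, cc - 1L)] - L[cbind(rr - 1L, cc + 1L)]) / 4
    det <- dxx * dyy - dxy^2
    aniso <- ifelse(det > 0 & (dxx + dyy) < 0, (dxx + dyy)^2 / det, Inf)
    out <- rbind(out, data.frame(
      x_m = scene$geotransform[1] + (cc - 0.5 + dc) * scene$geotransform[3],
      y_m = scene$geotransform[2] - (rr - 0.5 + dr) * scene$geotransform[4],
      sigma_m = sigmas_m[s] * ratio^ds,
      response = r0[idx],
      anisotropy = aniso))
  }
  out <- out[order(-out$response), , drop = FALSE]
  # exact response plateaus can surface twice; keep one detection each
  out <- out[!duplicated(round(cbind(out$x_m, out$y_m, out$sigma_m), 6)), ,
             drop = FALSE]
  if (nrow(out) > cfg$max_blobs) out <- out[seq_len(cfg$max_blobs), ]
  rownames(out) <- NULL
  out
}

#' Filter blobs to confident crown detections
#'
#' The full detection list deliberately includes weak responses; for tree
#' masking and ground-control extraction only confident, bell-shaped
#' crowns should be used. Keeps blobs whose response reaches
#' `min_response` and whose curvature anisotropy stays below
#' `max_anisotropy` (an isotropic Gaussian maximum scores exactly 4;
#' parcel corners, edges and other non-crown structures score higher).
#'
#' @param blobs blob data frame from [detect_blobs()].
#' @param min_response absolute response floor (a crown of amplitude A
#'   peaks near A/2).
#' @param max_anisotropy upper bound on the image-Hessian trace^2/det at
#'   the peak.
#' @return the filtered blob data frame.
#' @export
strong_blobs <- function(blobs, min_response = 0.04,
                         max_anisotropy = 4.1) {
  blobs[blobs$response >= min_response &
          blobs$anisotropy <= max_anisotropy, , drop = FALSE]
}
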