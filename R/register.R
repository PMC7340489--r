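# Co-registration of a scene stack onto a master image via tree-crown tie
# points: master selection by a shadow-length proxy, parallax adjustment of
# crown centroids, mutual-nearest-neighbour matching, robust consensus
# fitting of the geometric correction, and resampling onto the master grid.

#' Select the master scene of a site
#'
#' The master is the scene on which tree shadows are longest, proxied by
#' cot(sun elevation): shadow length scales with the cotangent of the solar
#' elevation, so the lowest sun wins. Ties break deterministically by
#' earliest acquisition time, then lexicographic scene id.
#'
#' @param metadata_list non-empty list of `ps_scene_meta`.
#' @return the selected `scene_id`.
#' @export
select_master <- function(metadata_list) {
  if (length(metadata_list) == 0L) stop("empty metadata list")
  proxy <- vapply(metadata_list, function(m)
    1 / tan(m$sun_elevation_deg * pi / 180), 0)
  times <- vapply(metadata_list, function(m)
    as.numeric(m$acquisition_time), 0)
  ids <- vapply(metadata_list, function(m) m$scene_id, "")
  ord <- order(-proxy, times, ids)
  ids[ord[1]]
}

#' Displace crown centroids to compensate parallax
#'
#' An elevated crown viewed off-nadir appears displaced by
#' `height x tan(off-nadir)` along the satellite azimuth; subtracting this
#' first-order displacement moves apparent centroids back over the trunk
#' before cross-scene matching.
#'
#' @param blobs blob data frame from [detect_blobs()].
#' @param meta the scene's `ps_scene_meta`.
#' @param canopy_height_m assumed canopy height (single value, metres).
#' @return the blob data frame with adjusted `x_m`, `y_m`.
#' @export
parallax_adjust <- function(blobs, meta, canopy_height_m = 10) {
  d <- canopy_height_m * tan(meta$sat_offnadir_deg * pi / 180)
  az <- meta$sat_azimuth_deg * pi / 180
  blobs$x_m <- blobs$x_m - d * sin(az)
  blobs$y_m <- blobs$y_m - d * cos(az)
  blobs
}

#' Match blob sets into tie-point pairs
#'
#' Pairs each target blob with the nearest master blob within
#' `search_radius_m` of the coarse-shift-adjusted target position, keeping
#' mutual nearest neighbours only, so pairing is one-to-one. The match
#' score is `min(response_m, response_t)` times a scale-similarity factor
#' `min(sigma_m, sigma_t) / max(sigma_m, sigma_t)`.
#'
#' @param master_blobs,target_blobs blob data frames.
#' @param search_radius_m pairing radius, metres (> 0).
#' @param coarse_shift_m optional a-priori (dx, dy) of the target relative
#'   to the master, subtracted before the distance search.
#' @return data frame with `master_x_m, master_y_m, target_x_m, target_y_m,
#'   match_score` (a `ps_tiepoints`).
#' @export
match_tiepoints <- function(master_blobs, target_blobs, search_radius_m,
                            coarse_shift_m = c(0, 0)) {
  if (search_radius_m <= 0) stop("search_radius_m must be positive")
  out <- data.frame(master_x_m = numeric(0), master_y_m = numeric(0),
                    target_x_m = numeric(0), target_y_m = numeric(0),
                    match_score = numeric(0))
  nm <- nrow(master_blobs); nt <- nrow(target_blobs)
  if (nm == 0L || nt == 0L) return(out)
  ax <- target_blobs$x_m - coarse_shift_m[1]
  ay <- target_blobs$y_m - coarse_shift_m[2]
  D2 <- outer(ax, master_blobs$x_m, `-`)^2 +
        outer(ay, master_blobs$y_m, `-`)^2
  nn_of_t <- apply(D2, 1L, which.min)        # nearest master per target
  nn_of_m <- apply(D2, 2L, which.min)        # nearest target per master
  keep <- which(D2[cbind(seq_len(nt), nn_of_t)] <= search_radius_m^2 &
                nn_of_m[nn_of_t] == seq_len(nt))
  if (!length(keep)) return(out)
  mi <- nn_of_t[keep]
  sim <- pmin(master_blobs$sigma_m[mi], target_blobs$sigma_m[keep]) /
         pmax(master_blobs$sigma_m[mi], target_blobs$sigma_m[keep])
  data.frame(master_x_m = master_blobs$x_m[mi],
             master_y_m = master_blobs$y_m[mi],
             target_x_m = target_blobs$x_m[keep],
             target_y_m = target_blobs$y_m[keep],
             match_score = pmin(master_blobs$response[mi],
                                target_blobs$response[keep]) * sim)
}

fit_translation <- function(pairs) {
  c(tx = mean(pairs$target_x_m - pairs$master_x_m),
    ty = mean(pairs$target_y_m - pairs$master_y_m))
}

# Least-squares affine target -> master: [mx, my] = A [tx, ty] + b.
fit_affine <- function(pairs) {
  X <- cbind(pairs$target_x_m, pairs$target_y_m, 1)
  qx <- qr(X)
  if (qx$rank < 3L) stop("degenerate geometry: tie points are collinear")
  cx <- qr.coef(qx, pairs$master_x_m)
  cy <- qr.coef(qx, pairs$master_y_m)
  c(a11 = cx[1], a12 = cx[2], b1 = cx[3],
    a21 = cy[1], a22 = cy[2], b2 = cy[3])
}

# Residuals (predicted master - master) per axis for either model.
correction_residuals <- function(pairs, model, par) {
  if (model == "translation") {
    cbind(dx = pairs$target_x_m - par[["tx"]] - pairs$master_x_m,
          dy = pairs$target_y_m - par[["ty"]] - pairs$master_y_m)
  } else {
    px <- par[["a11"]] * pairs$target_x_m + par[["a12"]] * pairs$target_y_m +
      par[["b1"]]
    py <- par[["a21"]] * pairs$target_x_m + par[["a22"]] * pairs$target_y_m +
      par[["b2"]]
    cbind(dx = px - pairs$master_x_m, dy = py - pairs$master_y_m)
  }
}

#' Estimate a robust geometric correction from tie points
#'
#' Random-sample consensus with a fixed seed: minimal samples (1 pair for
#' translation, 3 for affine) propose models, inliers fall within
#' `inlier_tol_m` of their prediction, and the model is refit by least
#' squares on the largest consensus set. The translation convention is
#' `target = master + (tx, ty)`; applying the correction removes the shift.
#'
#' Only the strongest candidate pairs serve as ground control: pairs are
#' ranked by match score and at most `max_gcps` enter the fit. After the
#' consensus stage the inlier set is polished by iterated trimming: refit,
#' halve the tolerance, re-select inliers (never below the model minimum),
#' for `refine_steps` rounds. Reported inliers/RMSE refer to the original
#' tolerance.
#'
#' @param pairs tie-point data frame from [match_tiepoints()].
#' @param model `"translation"` (default) or `"affine"`.
#' @param inlier_tol_m inlier distance tolerance, metres.
#' @param seed integer seed for the consensus sampling.
#' @param n_iter number of consensus iterations.
#' @param max_gcps use at most this many strongest pairs as GCPs.
#' @param refine_steps trimmed-refit rounds after consensus.
#' @return a `ps_correction`: `model`, `parameters`, `rmse_x_m`,
#'   `rmse_y_m`, `n_inliers`, `inliers` (row indices into `pairs`),
#'   `residuals_m` (per-pair signed dx, dy; NA for outliers).
#' @export
estimate_correction <- function(pairs, model = c("translation", "affine"),
                                inlier_tol_m = 3, seed = 1L,
                                n_iter = 500L, max_gcps = 20L,
                                refine_steps = 3L) {
  model <- match.arg(model)
  need <- if (model == "translation") 1L else 3L
  if (nrow(pairs) < need)
    stop("insufficient tie points: ", model, " needs at least ", need)
  ord <- order(-pairs$match_score, pairs$master_x_m, pairs$master_y_m)
  sel <- sort(ord[seq_len(min(length(ord), max_gcps))])
  pairs_all <- pairs
  pairs <- pairs[sel, , drop = FALSE]
  best_in <- integer(0)
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      take <- sample.int(nrow(pairs), need)
      par <- tryCatch({
        if (model == "translation") fit_translation(pairs[take, ])
        else fit_affine(pairs[take, ])
      }, error = function(e) NULL)
      if (is.null(par)) next
      res <- correction_residuals(pairs, model, par)
      inl <- which(sqrt(res[, 1]^2 + res[, 2]^2) <= inlier_tol_m)
      if (length(inl) > length(best_in)) best_in <- inl
    }
  })
  if (length(best_in) < need)
    stop("insufficient tie points: no consensus set of size ", need)
  refit <- function(inl) {
    if (model == "translation") fit_translation(pairs[inl, ])
    else fit_affine(pairs[inl, ])
  }
  par <- refit(best_in)
  tol <- inlier_tol_m
  for (k in seq_len(refine_steps)) {
    tol <- tol / 2
    res <- correction_residuals(pairs, model, par)
    inl <- which(sqrt(res[, 1]^2 + res[, 2]^2) <= tol)
    if (length(inl) < max(need, min(5L, length(best_in)))) break
    par <- refit(inl)
  }
  # report inliers and RMSE at the caller's tolerance (parameters stay at
  # the trimmed fit; re-admitting marginal pairs would re-bias it)
  res_all <- correction_residuals(pairs_all, model, par)
  d <- sqrt(res_all[, 1]^2 + res_all[, 2]^2)
  inliers <- which(d <= inlier_tol_m)
  res <- res_all
  res[setdiff(seq_len(nrow(pairs_all)), inliers), ] <- NA_real_
  structure(list(model = model, parameters = par,
                 rmse_x_m = sqrt(mean(res_all[inliers, 1]^2)),
                 rmse_y_m = sqrt(mean(res_all[inliers, 2]^2)),
                 n_inliers = length(inliers),
                 inliers = inliers,
                 residuals_m = res),
            class = "ps_correction")
}

#' @export
print.ps_correction <- function(x, ...) {
  cat("<ps_correction>", x$model, "\n  parameters:",
      paste(sprintf("%s=%.4f", names(x$parameters), x$parameters),
            collapse = " "), "\n")
  cat(sprintf("  %d inliers, RMSE (%.3f, %.3f) m\n", x$n_inliers,
              x$rmse_x_m, x$rmse_y_m))
  invisible(x)
}

#' Resample a scene onto the master grid under a fitted correction
#'
#' The output keeps the scene's grid (which is the master grid for
#' co-gridded stacks); every band is resampled identically, nodata
#' propagates, and pixels mapping outside the source become nodata.
#'
#' @param scene a `ps_scene`.
#' @param corr a `ps_correction` from [estimate_correction()].
#' @param resampling `"nearest"` or `"bilinear"`.
#' @return the corrected `ps_scene`.
#' @export
apply_correction <- function(scene, corr,
                             resampling = c("nearest", "bilinear")) {
  resampling <- match.arg(resampling)
  stopifnot(inherits(corr, "ps_correction"))
  p <- corr$parameters
  if (corr$model == "translation") {
    if (p[["tx"]] == 0 && p[["ty"]] == 0 && resampling == "nearest")
      return(scene)
    src_of <- function(xy) cbind(xy[, 1] + p[["tx"]], xy[, 2] + p[["ty"]])
  } else if (corr$model == "affine") {
    A <- rbind(c(p[["a11"]], p[["a12"]]), c(p[["a21"]], p[["a22"]]))
    Ainv <- solve(A)
    b <- c(p[["b1"]], p[["b2"]])
    src_of <- function(xy) t(Ainv %*% (t(xy) - b))
  } else stop("unsupported correction model: ", corr$model)
  resample_scene(scene, src_of, resampling)
}

#' Residual statistics against control points
#'
#' Compares scene-measured point locations with surveyed control locations
#' and reports the ten summary statistics conventionally tabulated for
#' geometric-accuracy assessments: mean and standard deviation of absolute
#' residuals per axis, min/max signed residuals per axis, and per-axis
#' RMSE. Standard deviations use the sample (n-1) denominator; RMSE is
#' root-mean-square of the signed residuals.
#'
#' @param scene_points,control_points n x 2 matrices of (x, y) metres,
#'   equal length, n >= 1.
#' @return named list: `mean_abs_dx`, `sd_abs_dx`, `mean_abs_dy`,
#'   `sd_abs_dy`, `min_dx`, `max_dx`, `min_dy`, `max_dy`, `rmse_x`,
#'   `rmse_y`.
#' @export
evaluate_against_controls <- function(scene_points, control_points) {
  scene_points <- as.matrix(scene_points)
  control_points <- as.matrix(control_points)
  if (nrow(scene_points) != nrow(control_points))
    stop("point lists differ in length")
  if (nrow(scene_points) < 1L) stop("need at least one control point")
  dx <- scene_points[, 1] - control_points[, 1]
  dy <- scene_points[, 2] - control_points[, 2]
  sd0 <- function(v) if (length(v) > 1L) stats::sd(v) else 0
  list(mean_abs_dx = mean(abs(dx)), sd_abs_dx = sd0(abs(dx)),
       mean_abs_dy = mean(abs(dy)), sd_abs_dy = sd0(abs(dy)),
       min_dx = min(dx), max_dx = max(dx),
       min_dy = min(dy), max_dy = max(dy),
       rmse_x = sqrt(mean(dx^2)), rmse_y = sqrt(mean(dy^2)))
}

#' One-call registration of a target scene onto a master
#'
#' Detects blobs on both scenes, discards anisotropic (non-crown-shaped)
#' detections, applies the parallax adjustment, matches tie points,
#' estimates the correction and resamples the target.
#'
#' @param master,target `ps_scene`s.
#' @param master_meta,target_meta optional `ps_scene_meta` for the
#'   parallax adjustment (skipped when `NULL`).
#' @param cfg a [detector_config()].
#' @param model correction model.
#' @param search_radius_m tie-point search radius, metres.
#' @param inlier_tol_m consensus inlier tolerance, metres.
#' @param canopy_height_m parallax canopy height, metres.
#' @param max_anisotropy curvature-anisotropy bound for tie-point
#'   candidates (see [strong_blobs()]).
#' @param resampling resampling kernel.
#' @param seed consensus seed.
#' @return list `scene` (registered target), `correction`, `tiepoints`.
#' @export
register_scene <- function(master, target, master_meta = NULL,
                           target_meta = NULL, cfg = detector_config(),
                           model = "translation", search_radius_m = 30,
                           inlier_tol_m = 3, canopy_height_m = 10,
                           max_anisotropy = 4.1,
                           resampling = "bilinear", seed = 1L) {
  mb <- detect_blobs(master, "nir1", cfg)
  tb <- detect_blobs(target, "nir1", cfg)
  mb <- mb[mb$anisotropy <= max_anisotropy, , drop = FALSE]
  tb <- tb[tb$anisotropy <= max_anisotropy, , drop = FALSE]
  if (!is.null(master_meta)) mb <- parallax_adjust(mb, master_meta,
                                                   canopy_height_m)
  if (!is.null(target_meta)) tb <- parallax_adjust(tb, target_meta,
                                                   canopy_height_m)
  pairs <- match_tiepoints(mb, tb, search_radius_m)
  corr <- estimate_correction(pairs, model = model,
                              inlier_tol_m = inlier_tol_m, seed = seed)
  list(scene = apply_correction(target, corr, resampling),
       correction = corr, tiepoints = pairs)
}
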