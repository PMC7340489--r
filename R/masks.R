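# Cloud and tree masks.
#
# Cloud masking assumes cloud pixels are the brightest blue-band pixels of
# the scene and takes the number of masked pixels from the provider
# metadata cloud percentage. Tree masking rasterizes discs around detected
# crown blobs on the master image, gated by a lowered NDVI threshold, and
# adapts the master mask to other acquisitions through the sensor-target
# geometry (canopy height x tan(off-nadir) along the satellite azimuth).

#' Tree-mask configuration
#'
#' @param ndvi_threshold NDVI gate; crowns below it are not masked. The
#'   default 0.2 is deliberately lower than the conventional 0.3
#'   vegetation cut, trading false positives for fewer missed crowns.
#' @param crown_radius_factor crown footprint radius as a multiple of the
#'   blob scale sigma (default 2: a Gaussian's visually apparent edge).
#' @param canopy_height_m assumed canopy height for geometric adaptation.
#' @return a `ps_tree_mask_config`.
#' @export
tree_mask_config <- function(ndvi_threshold = 0.2,
                             crown_radius_factor = 2,
                             canopy_height_m = 10) {
  if (crown_radius_factor <= 0) stop("crown_radius_factor must be > 0")
  if (ndvi_threshold < -1 || ndvi_threshold > 1)
    stop("ndvi_threshold must lie in [-1, 1]")
  structure(list(ndvi_threshold = ndvi_threshold,
                 crown_radius_factor = crown_radius_factor,
                 canopy_height_m = canopy_height_m),
            class = "ps_tree_mask_config")
}

#' Metadata-driven cloud mask
#'
#' Masks exactly the pixels whose blue reflectance strictly exceeds the
#' (1 - p/100) order-statistic quantile of the valid blue pixels, p being
#' the metadata cloud percentage. The strict inequality makes the mask
#' conservative under ties: the masked fraction never exceeds p/100.
#' Nodata pixels are never masked.
#'
#' @param scene a `ps_scene` with a blue band.
#' @param metadata the scene's `ps_scene_meta`.
#' @return a cloud `ps_mask`.
#' @export
cloud_mask <- function(scene, metadata) {
  blue <- scene_band(scene, "blue")
  p <- metadata$cloud_cover_pct
  if (p < 0 || p > 100) stop("cloud_cover_pct must be in [0, 100]")
  grid <- matrix(FALSE, nrow(blue), ncol(blue))
  valid <- !is.na(blue)
  if (any(valid) && p > 0) {
    thr <- stats::quantile(blue[valid], probs = 1 - p / 100,
                           type = 1, names = FALSE)
    grid[valid] <- blue[valid] > thr
  }
  mask_layer(grid, kind = "cloud", source_scene_id = scene$scene_id,
             geotransform = scene$geotransform)
}

#' Blob-based tree mask on the master image
#'
#' A pixel is masked iff its centre lies within
#' `crown_radius_factor x sigma` of some blob centroid and its NDVI
#' exceeds the (lowered) threshold.
#'
#' @param master the master `ps_scene` (red and nir1 bands required).
#' @param blobs blob data frame in master map coordinates.
#' @param cfg a [tree_mask_config()].
#' @return a tree `ps_mask`.
#' @export
tree_mask_master <- function(master, blobs, cfg = tree_mask_config()) {
  stopifnot(inherits(cfg, "ps_tree_mask_config"))
  red <- scene_band(master, "red")
  nir <- scene_band(master, "nir1")
  d <- dim(red)
  grid <- matrix(FALSE, d[1], d[2])
  gt <- master$geotransform
  if (nrow(blobs)) {
    for (k in seq_len(nrow(blobs))) {
      rad <- cfg$crown_radius_factor * blobs$sigma_m[k]
      r0 <- max(1L, floor((gt[2] - blobs$y_m[k] - rad) / gt[4]))
      r1 <- min(d[1], ceiling((gt[2] - blobs$y_m[k] + rad) / gt[4]))
      c0 <- max(1L, floor((blobs$x_m[k] - gt[1] - rad) / gt[3]))
      c1 <- min(d[2], ceiling((blobs$x_m[k] - gt[1] + rad) / gt[3]))
      if (r0 > r1 || c0 > c1) next
      rs <- r0:r1; cs <- c0:c1
      px <- gt[1] + (cs - 0.5) * gt[3]
      py <- gt[2] - (rs - 0.5) * gt[4]
      d2 <- outer((py - blobs$y_m[k])^2, (px - blobs$x_m[k])^2, `+`)
      grid[rs, cs] <- grid[rs, cs] | (d2 <= rad^2)
    }
  }
  ndvi <- (nir - red) / (nir + red)
  gate <- !is.na(ndvi) & ndvi > cfg$ndvi_threshold
  mask_layer(grid & gate, kind = "tree", source_scene_id = master$scene_id,
             geotransform = master$geotransform)
}

#' Adapt the master tree mask to another acquisition geometry
#'
#' Crowns appear displaced by `canopy_height x tan(off-nadir)` along the
#' satellite azimuth; the master mask is translated by that displacement,
#' rounded per axis to the nearest pixel. Pixels shifted off-grid are
#' dropped, so the mask never grows.
#'
#' @param master_mask the master tree `ps_mask` (needs its geotransform).
#' @param target_meta the target scene's `ps_scene_meta`.
#' @param cfg a [tree_mask_config()].
#' @return the adapted tree `ps_mask`.
#' @export
adapt_tree_mask <- function(master_mask, target_meta,
                            cfg = tree_mask_config()) {
  stopifnot(inherits(master_mask, "ps_mask"))
  if (target_meta$sat_offnadir_deg >= 90)
    stop("off-nadir angle must be below 90 degrees")
  gt <- master_mask$geotransform
  if (is.null(gt)) stop("master mask lacks a geotransform")
  d <- cfg$canopy_height_m * tan(target_meta$sat_offnadir_deg * pi / 180)
  az <- target_meta$sat_azimuth_deg * pi / 180
  dc <- round(d * sin(az) / gt[3])
  dr <- round(-d * cos(az) / gt[4])
  g <- master_mask$grid
  nr <- nrow(g); nc <- ncol(g)
  out <- matrix(FALSE, nr, nc)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- g[src_r[ok_r], src_c[ok_c]]
  mask_layer(out, kind = "tree", source_scene_id = master_mask$source_scene_id,
             geotransform = gt)
}

#' Combine masks by pixelwise OR
#'
#' @param masks non-empty list of `ps_mask` with equal dimensions.
#' @return a combined `ps_mask`.
#' @export
combine_masks <- function(masks) {
  if (length(masks) == 0L) stop("no masks to combine")
  dims <- unique(lapply(masks, function(m) dim(m$grid)))
  if (length(dims) != 1L) stop("mask dimensions differ")
  if (length(masks) == 1L) return(masks[[1]])
  grid <- Reduce(`|`, lapply(masks, `[[`, "grid"))
  mask_layer(grid, kind = "combined",
             source_scene_id = masks[[1]]$source_scene_id,
             geotransform = masks[[1]]$geotransform)
}
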