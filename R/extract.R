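# Full per-scene, per-field signature extraction: one spectral record per
# field (moments, correlation/covariance, vegetation-index summaries) and
# eight texture records per field, as flat rows ready for the CSV writers.

#' Extract all per-field signatures from a co-registered scene
#'
#' Applies the negative boundary buffer to every field, selects unmasked
#' pixels, and computes the spectral moments, band correlation/covariance,
#' vegetation-index summaries and co-occurrence texture descriptors. A
#' field fully masked out (or collapsed by the buffer) still yields a
#' record, with counts present and statistics NA.
#'
#' @param scene a co-registered `ps_scene`.
#' @param metadata the scene's `ps_scene_meta` (timestamps the records).
#' @param fields list of `ps_field`.
#' @param masks list of `ps_mask` to combine and apply (may be empty).
#' @param buffer_m inward boundary buffer in metres (default 2).
#' @param params a [vi_params()].
#' @param texture_band band role for texture (default panchromatic,
#'   falling back to nir1 when absent).
#' @param distance_px co-occurrence displacement.
#' @return `list(spectral = <records>, texture = <records>)`.
#' @export
extract_all <- function(scene, metadata, fields, masks = list(),
                        buffer_m = 2, params = vi_params(),
                        texture_band = NULL, distance_px = 1L) {
  mask <- if (length(masks)) combine_masks(masks) else NULL
  if (is.null(texture_band))
    texture_band <- if ("pan" %in% names(scene$bands)) "pan" else "nir1"
  date <- format(metadata$acquisition_time, "%Y-%m-%d")
  roles <- names(scene$bands)
  spectral <- vector("list", length(fields))
  texture <- list()
  for (fi in seq_along(fields)) {
    f <- fields[[fi]]
    fb <- buffer_field(f, buffer_m)
    px <- field_pixels(scene, fb, mask)
    vals <- lapply(scene$bands, function(b) b[px$used])
    mom <- spectral_moments(vals)
    rec <- list(scene_id = scene$scene_id, field_id = f$field_id,
                crop = f$crop, date = date,
                n_total = length(px$total), n_used = length(px$used))
    for (r in roles) {
      rec[[paste0(r, "_mean")]] <- mom$mean[[r]]
      rec[[paste0(r, "_var")]] <- mom$variance[[r]]
      rec[[paste0(r, "_skew")]] <- mom$skewness[[r]]
    }
    if (length(roles) > 1L) {
      for (a in seq_len(length(roles) - 1L)) for (b in (a + 1L):length(roles))
        rec[[paste0("corr_", roles[a], "_", roles[b])]] <-
          mom$corr[roles[a], roles[b]]
      for (a in seq_len(length(roles) - 1L)) for (b in (a + 1L):length(roles))
        rec[[paste0("cov_", roles[a], "_", roles[b])]] <-
          mom$cov[roles[a], roles[b]]
    }
    vis <- field_vi_summary(scene, fb, mask, params)
    for (v in names(vis)) {
      rec[[paste0(v, "_mean")]] <- vis[[v]]$mean
      rec[[paste0(v, "_sd")]] <- vis[[v]]$sd
    }
    spectral[[fi]] <- rec
    tr <- field_texture(scene, fb, mask, band_role = texture_band,
                        distance_px = distance_px)
    tr <- lapply(tr, function(x) { x$field_id <- f$field_id; x })
    texture <- c(texture, tr)
  }
  list(spectral = spectral, texture = texture)
}
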