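# Grid resampling shared by shift_scene() and apply_correction().
# Source positions are fractional (row, col) indices; anything outside the
# source grid, and any NA touched by interpolation, becomes NA.

sample_grid <- function(mat, src_row, src_col,
                        resampling = c("nearest", "bilinear")) {
  resampling <- match.arg(resampling)
  nr <- nrow(mat); nc <- ncol(mat)
  out <- rep(NA_real_, length(src_row))
  if (resampling == "nearest") {
    r <- round(src_row); c <- round(src_col)
    ok <- !is.na(r) & !is.na(c) & r >= 1 & r <= nr & c >= 1 & c <= nc
    out[ok] <- mat[cbind(r[ok], c[ok])]
  } else {
    r0 <- floor(src_row); c0 <- floor(src_col)
    fr <- src_row - r0; fc <- src_col - c0
    # positions exactly on the last grid line interpolate from the cell above
    hi_r <- !is.na(src_row) & src_row == nr
    r0[hi_r] <- nr - 1; fr[hi_r] <- 1
    hi_c <- !is.na(src_col) & src_col == nc
    c0[hi_c] <- nc - 1; fc[hi_c] <- 1
    ok <- !is.na(r0) & !is.na(c0) &
      r0 >= 1 & (r0 + 1) <= nr & c0 >= 1 & (c0 + 1) <= nc
    i <- which(ok)
    if (length(i)) {
      v00 <- mat[cbind(r0[i], c0[i])]
      v01 <- mat[cbind(r0[i], c0[i] + 1)]
      v10 <- mat[cbind(r0[i] + 1, c0[i])]
      v11 <- mat[cbind(r0[i] + 1, c0[i] + 1)]
      out[i] <- (1 - fr[i]) * ((1 - fc[i]) * v00 + fc[i] * v01) +
                fr[i] * ((1 - fc[i]) * v10 + fc[i] * v11)
    }
  }
  out
}

# Resample every band of `scene` so that the value at map coordinate p is
# taken from the source at src_of(p); src_of returns an n x 2 (x, y) matrix.
resample_scene <- function(scene, src_of, resampling) {
  d <- scene_dim(scene)
  rc <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  ctr <- pixel_centre_xy(scene, rc$row, rc$col)
  src_xy <- src_of(ctr)
  src <- map_to_rowcol(scene, src_xy[, 1], src_xy[, 2])
  bands <- lapply(scene$bands, function(b) {
    matrix(sample_grid(b, src[, 1], src[, 2], resampling), d[1], d[2])
  })
  scene(bands, geotransform = scene$geotransform, crs_id = scene$crs_id,
        scene_id = scene$scene_id)
}
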