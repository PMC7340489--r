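# Raster, vector and table I/O.
#
# Scenes and masks are stored as multi-page float32/8-bit TIFF with a JSON
# sidecar (<path>.aux.json) carrying the geotransform, CRS id, band roles and
# nodata convention; an extra "validity" page marks nodata pixels (1 = valid).
# Field polygons travel as GeoJSON, acquisition metadata and ground truth as
# JSON, signature records as CSV.

sidecar_path <- function(path) paste0(path, ".aux.json")

#' Write a scene to disk
#'
#' One float32 TIFF page per band plus a trailing validity page (1 = valid,
#' 0 = nodata), with georeferencing in a JSON sidecar next to the raster.
#'
#' @param scene a `ps_scene`.
#' @param path output raster path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "ps_scene"))
  valid <- Reduce(`&`, lapply(scene$bands, function(b) !is.na(b)))
  pages <- lapply(scene$bands, function(b) {
    b[is.na(b)] <- 0
    b
  })
  pages <- c(pages, list(valid * 1))
  ok <- try(tiff::writeTIFF(unname(pages), path, bits.per.sample = 32L,
                            reduce = FALSE), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("I/O error writing scene to '", path, "'")
  aux <- list(format = "parcelscope-scene-v1",
              band_roles = names(scene$bands),
              geotransform = scene$geotransform,
              crs_id = scene$crs_id,
              scene_id = scene$scene_id,
              validity_page = length(pages))
  jsonlite::write_json(aux, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a scene (and optionally its acquisition metadata)
#'
#' @param path raster path written by [write_scene()].
#' @param metadata_path optional path to a metadata JSON written by
#'   [write_scene_metadata()].
#' @return the `ps_scene`, or `list(scene, metadata)` when `metadata_path`
#'   is given.
#' @export
read_scene <- function(path, metadata_path = NULL) {
  if (!file.exists(path)) stop("no such raster: ", path)
  if (!file.exists(sidecar_path(path)))
    stop("missing georeferencing sidecar for ", path)
  aux <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  roles <- aux$band_roles
  if (length(pages) != length(roles) + 1L)
    stop("scene schema error: page count does not match sidecar band roles")
  valid <- pages[[length(pages)]] > 0.5
  bands <- stats::setNames(pages[seq_along(roles)], roles)
  bands <- lapply(bands, function(b) { b[!valid] <- NA_real_; b })
  sc <- scene(bands, geotransform = as.numeric(aux$geotransform),
              crs_id = aux$crs_id, scene_id = aux$scene_id)
  if (is.null(metadata_path)) return(sc)
  list(scene = sc, metadata = read_scene_metadata(metadata_path))
}

#' Write / read acquisition metadata as JSON
#' @param meta a `ps_scene_meta`.
#' @param path JSON path.
#' @return `path` / the `ps_scene_meta`.
#' @export
write_scene_metadata <- function(meta, path) {
  stopifnot(inherits(meta, "ps_scene_meta"))
  out <- unclass(meta)
  out$acquisition_time <- format(meta$acquisition_time,
                                 "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scene_metadata
#' @export
read_scene_metadata <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  scene_metadata(scene_id = x$scene_id,
                 acquisition_time = x$acquisition_time,
                 sun_elevation_deg = x$sun_elevation_deg,
                 sun_azimuth_deg = x$sun_azimuth_deg,
                 sat_offnadir_deg = x$sat_offnadir_deg,
                 sat_azimuth_deg = x$sat_azimuth_deg,
                 cloud_cover_pct = x$cloud_cover_pct,
                 sensor = x$sensor)
}

#' Write / read a mask raster
#'
#' Stored as a single 8-bit TIFF page (1 = masked) with a JSON sidecar.
#'
#' @param mask a `ps_mask`.
#' @param path output path.
#' @return `path` / the `ps_mask`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "ps_mask"))
  tiff::writeTIFF(mask$grid * 1, path, bits.per.sample = 8L)
  aux <- list(format = "parcelscope-mask-v1", kind = mask$kind,
              source_scene_id = mask$source_scene_id,
              geotransform = mask$geotransform)
  jsonlite::write_json(aux, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  aux <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  g <- tiff::readTIFF(path)
  mask_layer(g > 0.5, kind = aux$kind,
             source_scene_id = aux$source_scene_id,
             geotransform = if (is.null(aux$geotransform)) NULL
                            else as.numeric(aux$geotransform))
}

#' Write / read field polygons as GeoJSON
#'
#' Coordinates are in the scene CRS (projected metres); the CRS id is
#' recorded as a foreign member of the FeatureCollection.
#'
#' @param fields list of `ps_field`.
#' @param path GeoJSON path.
#' @param crs_id CRS identifier recorded in the file.
#' @return `path` / list of `ps_field`.
#' @export
write_fields_geojson <- function(fields, path, crs_id = "EPSG:32630") {
  feats <- lapply(fields, function(f) {
    ring <- rbind(f$ring, f$ring[1, ])  # GeoJSON rings are closed
    list(type = "Feature",
         properties = list(field_id = f$field_id, crop = f$crop),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(i) as.numeric(ring[i, ])))))
  })
  fc <- list(type = "FeatureCollection", crs_id = crs_id, features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fields_geojson
#' @export
read_fields_geojson <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(fc$features, function(ft) {
    ring <- do.call(rbind, lapply(ft$geometry$coordinates[[1]],
                                  function(p) unlist(p)[1:2]))
    field_polygon(field_id = ft$properties$field_id,
                  crop = ft$properties$crop, ring = ring)
  })
}

#' Mosaic co-gridded tiles into a single scene
#'
#' Tiles must share CRS, band roles and pixel size, and their origins must
#' differ by whole pixel multiples. The output extent is the union bounding
#' box; where tiles overlap, the first tile in input order wins; pixels
#' covered by no tile are nodata.
#'
#' @param tiles list of `ps_scene`.
#' @return the mosaicked `ps_scene`.
#' @export
stitch_tiles <- function(tiles) {
  if (length(tiles) == 0L) stop("no tiles to stitch")
  if (length(tiles) == 1L) return(tiles[[1]])
  ref <- tiles[[1]]
  pw <- ref$geotransform[3]; ph <- ref$geotransform[4]
  for (t in tiles) {
    if (!identical(names(t$bands), names(ref$bands)) ||
        t$crs_id != ref$crs_id)
      stop("incompatible tiles: band roles or CRS differ")
    if (abs(t$geotransform[3] - pw) > 1e-9 ||
        abs(t$geotransform[4] - ph) > 1e-9)
      stop("incompatible tiles: pixel sizes differ")
  }
  ox <- min(vapply(tiles, function(t) t$geotransform[1], 0))
  oy <- max(vapply(tiles, function(t) t$geotransform[2], 0))
  offs <- lapply(tiles, function(t) {
    dc <- (t$geotransform[1] - ox) / pw
    dr <- (oy - t$geotransform[2]) / ph
    if (abs(dc - round(dc)) > 1e-6 || abs(dr - round(dr)) > 1e-6)
      stop("tile grids are not aligned to whole pixels")
    c(row = round(dr), col = round(dc))
  })
  nr <- max(vapply(seq_along(tiles), function(i)
    offs[[i]]["row"] + nrow(tiles[[i]]$bands[[1]]), 0))
  nc <- max(vapply(seq_along(tiles), function(i)
    offs[[i]]["col"] + ncol(tiles[[i]]$bands[[1]]), 0))
  bands <- lapply(names(ref$bands), function(role) {
    out <- matrix(NA_real_, nr, nc)
    for (i in seq_along(tiles)) {
      b <- tiles[[i]]$bands[[role]]
      rs <- offs[[i]]["row"] + seq_len(nrow(b))
      cs <- offs[[i]]["col"] + seq_len(ncol(b))
      blank <- is.na(out[rs, cs])
      patch <- out[rs, cs]
      patch[blank] <- b[blank]
      out[rs, cs] <- patch
    }
    out
  })
  scene(stats::setNames(bands, names(ref$bands)),
        geotransform = c(ox, oy, pw, ph), crs_id = ref$crs_id,
        scene_id = ref$scene_id)
}

fmt_cell <- function(x) {
  if (is.na(x)) return("")
  if (is.numeric(x)) return(sprintf("%.10g", x))
  as.character(x)
}

write_record_csv <- function(records, path, fixed_header) {
  if (length(records) == 0L) {
    writeLines(paste(fixed_header, collapse = ","), path)
    return(invisible(path))
  }
  ids <- vapply(records, function(r) as.character(r$scene_id), "")
  if (length(unique(ids)) != 1L)
    stop("records mix scene_ids; one CSV per image")
  cols <- names(records[[1]])
  lines <- vapply(records, function(r) {
    paste(vapply(cols, function(cn) fmt_cell(r[[cn]]), ""), collapse = ",")
  }, "")
  writeLines(c(paste(cols, collapse = ","), lines), path)
  invisible(path)
}

#' Write per-field spectral signature records to CSV
#'
#' Columns: `scene_id,field_id,crop,date,n_total,n_used`, then per band
#' `{band}_mean,{band}_var,{band}_skew`, band-pair `corr_{i}_{j}` and
#' `cov_{i}_{j}` (i < j in band order), then `{index}_mean,{index}_sd` per
#' vegetation index. Undefined statistics are empty cells; numbers carry at
#' least 9 significant digits.
#'
#' @param records list of flat spectral records from [extract_all()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_spectral_csv <- function(records, path) {
  write_record_csv(records, path,
                   c("scene_id", "field_id", "crop", "date",
                     "n_total", "n_used"))
}

.TEXTURE_HEADER <- c("scene_id", "field_id", "grey_levels", "angle_deg",
                     "f_asm", "f_contrast", "f_correlation", "f_variance",
                     "f_homogeneity", "f_sum_avg", "f_sum_var",
                     "f_sum_entropy", "f_entropy", "f_diff_var",
                     "f_diff_entropy", "f_imc", "f_max_corr_coeff",
                     "f_imc2")

#' Write per-field texture records to CSV
#'
#' One row per field, grey-level setting and co-occurrence angle, holding
#' the thirteen Haralick descriptors (plus the auxiliary second information
#' measure of correlation, `f_imc2`).
#'
#' @inheritParams write_spectral_csv
#' @export
write_texture_csv <- function(records, path) {
  write_record_csv(records, path, .TEXTURE_HEADER)
}
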