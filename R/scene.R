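# Band roles recognised throughout the package. blue/green/red/nir1 are
# mandatory for a valid scene; the rest are optional (4-, 5- and 8-band
# sensors plus a panchromatic channel).
.BAND_ROLES <- c("blue", "green", "red", "rededge", "nir1", "nir2",
                 "cyan", "yellow", "pan")
.MANDATORY_ROLES <- c("blue", "green", "red", "nir1")

#' Construct a multispectral scene
#'
#' A scene holds one 2-D surface-reflectance matrix per band (north-up,
#' row 1 = northern edge), a band-role map, an affine north-up geotransform
#' and a CRS identifier. Reflectance is unitless in [0, 1]; missing pixels
#' are `NA`.
#'
#' Coordinate convention: `geotransform = c(origin_x, origin_y, pixel_w,
#' pixel_h)` where `(origin_x, origin_y)` is the map coordinate of the
#' *top-left corner* of pixel (row 1, col 1) and pixel sizes are positive
#' metres. The map coordinate *of* a pixel always refers to its centre:
#' `x = origin_x + (col - 0.5) * pixel_w`, `y = origin_y - (row - 0.5) *
#' pixel_h`.
#'
#' @param bands named list of equally sized numeric matrices, one per band
#'   role (names drawn from blue, green, red, rededge, nir1, nir2, cyan,
#'   yellow, pan).
#' @param geotransform numeric length-4: origin_x, origin_y (metres, map
#'   units of a projected CRS), pixel_w, pixel_h (metres, > 0).
#' @param crs_id CRS identifier string for a projected CRS, e.g.
#'   `"EPSG:32630"`.
#' @param scene_id optional identifier carried through to outputs.
#' @return an object of class `ps_scene`.
#' @export
scene <- function(bands, geotransform, crs_id = "EPSG:32630",
                  scene_id = NULL) {
  if (!is.list(bands) || length(bands) == 0L || is.null(names(bands)))
    stop("'bands' must be a non-empty named list of matrices")
  roles <- names(bands)
  bad <- setdiff(roles, .BAND_ROLES)
  if (length(bad))
    stop("unknown band role(s): ", paste(bad, collapse = ", "))
  missing_roles <- setdiff(.MANDATORY_ROLES, roles)
  if (length(missing_roles))
    stop("scene schema error: missing mandatory band role(s): ",
         paste(missing_roles, collapse = ", "))
  dims <- unique(lapply(bands, dim))
  if (length(dims) != 1L)
    stop("all bands must share dimensions")
  for (r in roles) {
    v <- bands[[r]]
    if (!is.numeric(v) || is.null(dim(v)))
      stop("band '", r, "' is not a numeric matrix")
    rng <- range(v, na.rm = TRUE)
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
      stop("band '", r, "' has reflectance outside [0, 1]")
  }
  geotransform <- as.numeric(geotransform)
  if (length(geotransform) != 4L || any(!is.finite(geotransform)) ||
      geotransform[3] <= 0 || geotransform[4] <= 0)
    stop("'geotransform' must be c(origin_x, origin_y, pixel_w > 0, pixel_h > 0)")
  if (grepl("^EPSG:4326$|geographic", crs_id, ignore.case = TRUE))
    stop("unsupported CRS: scenes must use a projected CRS in metres")
  structure(list(bands = bands,
                 band_map = stats::setNames(seq_along(bands), roles),
                 geotransform = geotransform,
                 crs_id = crs_id,
                 scene_id = scene_id),
            class = "ps_scene")
}

#' @export
print.ps_scene <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat("<ps_scene>", if (!is.null(x$scene_id)) x$scene_id else "", "\n")
  cat(sprintf("  %d x %d px, %d band(s): %s\n", d[1], d[2],
              length(x$bands), paste(names(x$bands), collapse = ", ")))
  cat(sprintf("  pixel %.3g x %.3g m, origin (%.2f, %.2f), %s\n",
              x$geotransform[3], x$geotransform[4],
              x$geotransform[1], x$geotransform[2], x$crs_id))
  invisible(x)
}

scene_dim <- function(scene) dim(scene$bands[[1]])

#' Get a band matrix by role
#' @param scene a `ps_scene`.
#' @param role band role string.
#' @return the reflectance matrix.
#' @export
scene_band <- function(scene, role) {
  if (!role %in% names(scene$bands))
    stop("band role '", role, "' not present in scene")
  scene$bands[[role]]
}

# Map coordinates of pixel centres. rows/cols are 1-based indices.
pixel_centre_xy <- function(scene, rows, cols) {
  gt <- scene$geotransform
  cbind(x = gt[1] + (cols - 0.5) * gt[3],
        y = gt[2] - (rows - 0.5) * gt[4])
}

# Fractional (row, col) of a map coordinate; centre of pixel (1,1) maps to
# (1, 1) exactly.
map_to_rowcol <- function(scene, x, y) {
  gt <- scene$geotransform
  cbind(row = (gt[2] - y) / gt[4] + 0.5,
        col = (x - gt[1]) / gt[3] + 0.5)
}

#' Construct scene acquisition metadata
#'
#' @param scene_id identifier string.
#' @param acquisition_time POSIXct or ISO-8601 string (UTC).
#' @param sun_elevation_deg solar elevation above horizon, (0, 90].
#' @param sun_azimuth_deg solar azimuth, degrees clockwise from north.
#' @param sat_offnadir_deg sensor off-nadir angle, [0, 90).
#' @param sat_azimuth_deg sensor azimuth, degrees clockwise from north.
#' @param cloud_cover_pct provider-reported cloud percentage, [0, 100].
#' @param sensor sensor family label.
#' @return an object of class `ps_scene_meta`.
#' @export
scene_metadata <- function(scene_id, acquisition_time,
                           sun_elevation_deg, sun_azimuth_deg = 0,
                           sat_offnadir_deg = 0, sat_azimuth_deg = 0,
                           cloud_cover_pct = 0,
                           sensor = c("synthetic", "WV2", "WV3", "GeoEye",
                                      "QuickBird", "RapidEye")) {
  sensor <- match.arg(sensor)
  if (is.character(acquisition_time))
    acquisition_time <- as.POSIXct(acquisition_time, tz = "UTC")
  if (!(sun_elevation_deg > 0 && sun_elevation_deg <= 90))
    stop("sun_elevation_deg must be in (0, 90]")
  if (cloud_cover_pct < 0 || cloud_cover_pct > 100)
    stop("cloud_cover_pct must be in [0, 100]")
  if (sat_offnadir_deg < 0 || sat_offnadir_deg >= 90)
    stop("sat_offnadir_deg must be in [0, 90)")
  structure(list(scene_id = scene_id,
                 acquisition_time = acquisition_time,
                 sun_elevation_deg = sun_elevation_deg,
                 sun_azimuth_deg = sun_azimuth_deg,
                 sat_offnadir_deg = sat_offnadir_deg,
                 sat_azimuth_deg = sat_azimuth_deg,
                 cloud_cover_pct = cloud_cover_pct,
                 sensor = sensor),
            class = "ps_scene_meta")
}

#' Construct a farm-field polygon
#'
#' @param field_id identifier string.
#' @param crop crop label string.
#' @param ring n x 2 matrix of (x, y) map-metre vertices; open (no repeated
#'   last vertex) or closed, non-self-intersecting, at least 3 distinct
#'   vertices, positive area.
#' @return an object of class `ps_field` with an open ring.
#' @export
field_polygon <- function(field_id, crop, ring) {
  ring <- as.matrix(ring)
  if (ncol(ring) != 2L) stop("ring must be an n x 2 matrix")
  n <- nrow(ring)
  if (n >= 2 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  if (nrow(unique(ring)) < 3L)
    stop("field polygon needs at least 3 distinct vertices")
  if (abs(polygon_area(ring)) <= 0)
    stop("field polygon must have positive area")
  structure(list(field_id = field_id, crop = crop, ring = ring),
            class = "ps_field")
}

#' Construct a boolean mask aligned to a scene grid
#'
#' @param grid logical matrix, `TRUE` = masked out.
#' @param kind one of `"cloud"`, `"tree"`, `"combined"`.
#' @param source_scene_id id of the scene the mask was derived from.
#' @param geotransform geotransform of the aligned grid.
#' @return an object of class `ps_mask`.
#' @export
mask_layer <- function(grid, kind = c("cloud", "tree", "combined"),
                       source_scene_id = NULL, geotransform = NULL) {
  kind <- match.arg(kind)
  if (!is.logical(grid) || is.null(dim(grid)))
    stop("'grid' must be a logical matrix")
  structure(list(grid = grid, kind = kind,
                 source_scene_id = source_scene_id,
                 geotransform = geotransform),
            class = "ps_mask")
}

#' @export
print.ps_mask <- function(x, ...) {
  cat(sprintf("<ps_mask:%s> %d x %d px, %d masked (%.2f%%)\n", x$kind,
              nrow(x$grid), ncol(x$grid), sum(x$grid),
              100 * mean(x$grid)))
  invisible(x)
}
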