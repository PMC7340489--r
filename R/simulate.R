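# Synthetic-scene generator.
#
# Emulates the landscape the workflow targets: homogeneous smallholder crop
# parcels on a soil background, isolated tree crowns rendered as additive
# isotropic 2-D Gaussian bumps (a bell-shaped intensity surface) on the NIR,
# green and panchromatic bands, bright connected cloud patches whose blue
# reflectance strictly exceeds every background pixel, additive Gaussian
# sensor noise, and a known inter-scene translation. Every injected feature
# is recorded as ground truth so detection, masking and registration can be
# scored exactly.

.SIM_SOIL <- c(blue = 0.10, green = 0.14, red = 0.18, rededge = 0.22,
               nir1 = 0.25, nir2 = 0.26, pan = 0.16)
.SIM_FIELD <- c(blue = 0.06, green = 0.10, red = 0.08, rededge = 0.25,
                nir1 = 0.40, nir2 = 0.42, pan = 0.20)

# Run `expr` under a private RNG stream without disturbing the caller's.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration for the synthetic-scene generator
#'
#' Defaults describe a 128 x 128 px scene at 2 m ground sampling distance
#' (256 m on a side) with a dozen isolated tree crowns of 4-8 m scale and
#' 0.15 reflectance amplitude over a 1% noise floor, five rectangular crop
#' parcels, and no clouds. These are the study conditions every downstream
#' module is exercised against.
#'
#' @param width_px,height_px scene size in pixels (>= 32).
#' @param gsd_m ground sampling distance, metres/pixel.
#' @param origin_xy map coordinate (metres) of the top-left scene corner.
#' @param n_trees number of tree crowns.
#' @param crown_sigma_range_m (min, max) crown Gaussian scale, metres.
#' @param crown_amplitude added NIR/green reflectance at a crown apex.
#' @param n_fields number of rectangular crop parcels.
#' @param field_reflectance named per-band parcel reflectance in [0, 1].
#' @param noise_sd additive Gaussian noise s.d. (reflectance units).
#' @param cloud_fraction fraction of pixels covered by cloud, [0, 1].
#' @param shift_xy_m translation recorded as the scene's ground-truth shift.
#' @param bands band roles to render.
#' @param seed integer layout seed (crowns, parcels, cloud placement).
#' @param noise_seed integer noise seed; defaults to `seed`. Keeping the
#'   layout seed fixed while varying `noise_seed` produces repeat
#'   acquisitions of the same ground.
#' @param sun_elevation_deg,sun_azimuth_deg,sat_offnadir_deg,sat_azimuth_deg
#'   acquisition geometry written to the scene metadata.
#' @return a validated `ps_sim_config` list.
#' @export
sim_config <- function(width_px = 128L, height_px = 128L, gsd_m = 2,
                       origin_xy = c(500000, 1500000),
                       n_trees = 12L, crown_sigma_range_m = c(4, 7),
                       crown_amplitude = 0.15,
                       n_fields = 5L, field_reflectance = .SIM_FIELD,
                       noise_sd = 0.01, cloud_fraction = 0,
                       shift_xy_m = c(0, 0),
                       bands = c("blue", "green", "red", "rededge",
                                 "nir1", "nir2", "pan"),
                       seed = 1L, noise_seed = NULL,
                       sun_elevation_deg = 55, sun_azimuth_deg = 130,
                       sat_offnadir_deg = 12, sat_azimuth_deg = 80) {
  cfg <- list(width_px = as.integer(width_px),
              height_px = as.integer(height_px),
              gsd_m = gsd_m, origin_xy = as.numeric(origin_xy),
              n_trees = as.integer(n_trees),
              crown_sigma_range_m = as.numeric(crown_sigma_range_m),
              crown_amplitude = crown_amplitude,
              n_fields = as.integer(n_fields),
              field_reflectance = field_reflectance,
              noise_sd = noise_sd, cloud_fraction = cloud_fraction,
              shift_xy_m = as.numeric(shift_xy_m), bands = bands,
              seed = as.integer(seed),
              noise_seed = if (is.null(noise_seed)) as.integer(seed)
                           else as.integer(noise_seed),
              sun_elevation_deg = sun_elevation_deg,
              sun_azimuth_deg = sun_azimuth_deg,
              sat_offnadir_deg = sat_offnadir_deg,
              sat_azimuth_deg = sat_azimuth_deg)
  check <- function(ok, field, why)
    if (!ok) stop("invalid sim config field '", field, "': ", why)
  check(cfg$width_px >= 32 && cfg$height_px >= 32, "width_px/height_px",
        "scene must be at least 32 px on a side")
  check(cfg$gsd_m > 0, "gsd_m", "must be positive")
  check(cfg$cloud_fraction >= 0 && cfg$cloud_fraction <= 1,
        "cloud_fraction", "must lie in [0, 1]")
  check(cfg$crown_sigma_range_m[1] <= cfg$crown_sigma_range_m[2] &&
          cfg$crown_sigma_range_m[1] > 0,
        "crown_sigma_range_m", "need 0 < min <= max")
  check(all(cfg$field_reflectance >= 0 & cfg$field_reflectance <= 1),
        "field_reflectance", "reflectance must lie in [0, 1]")
  check(cfg$crown_amplitude >= 0 && cfg$crown_amplitude <= 1,
        "crown_amplitude", "must lie in [0, 1]")
  check(cfg$noise_sd >= 0, "noise_sd", "must be non-negative")
  check(cfg$n_trees >= 0, "n_trees", "must be non-negative")
  check(cfg$n_fields >= 0, "n_fields", "must be non-negative")
  check(all(.MANDATORY_ROLES %in% cfg$bands), "bands",
        "blue, green, red, nir1 are mandatory")
  structure(cfg, class = "ps_sim_config")
}

dist_point_segment <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  t <- ((px - ax) * vx + (py - ay) * vy) / (vx^2 + vy^2)
  t <- pmin(pmax(t, 0), 1)
  sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
}

min_dist_to_rings <- function(x, y, fields) {
  if (length(fields) == 0L) return(Inf)
  mind <- Inf
  for (f in fields) {
    r <- f$ring
    n <- nrow(r)
    j <- c(seq_len(n)[-1], 1L)
    mind <- min(mind, dist_point_segment(x, y, r[, 1], r[, 2],
                                         r[j, 1], r[j, 2]))
  }
  mind
}

# Rejection-sample crown centres with mutual separation >= 6 * sigma_max, an
# edge margin, and clearance from parcel boundaries: a crown straddling a
# reflectance step is no longer a clean bell-shaped surface (the regime the
# detector is specified for is isolated crowns).
place_crowns <- function(cfg, width_m, height_m, fields = list()) {
  if (cfg$n_trees == 0L)
    return(data.frame(x_m = numeric(0), y_m = numeric(0),
                      sigma_m = numeric(0), height_m = numeric(0)))
  sig <- stats::runif(cfg$n_trees, cfg$crown_sigma_range_m[1],
                      cfg$crown_sigma_range_m[2])
  hgt <- stats::runif(cfg$n_trees, 8, 12)
  xs <- ys <- numeric(0)
  tries <- 0L
  for (k in seq_len(cfg$n_trees)) {
    margin <- 3 * sig[k]
    clear <- 3.5 * sig[k]
    repeat {
      tries <- tries + 1L
      if (tries > 50000L)
        stop("invalid sim config field 'n_trees': cannot place ",
             cfg$n_trees, " isolated crowns in this scene")
      x <- cfg$origin_xy[1] + margin +
        stats::runif(1) * (width_m - 2 * margin)
      y <- cfg$origin_xy[2] - margin -
        stats::runif(1) * (height_m - 2 * margin)
      if (min_dist_to_rings(x, y, fields) < clear ||
          any(vapply(fields, function(f)
            points_in_polygon(x, y, f$ring), FALSE))) next
      if (length(xs)) {
        sep <- 6 * pmax(sig[k], sig[seq_along(xs)])
        if (any((xs - x)^2 + (ys - y)^2 < sep^2)) next
      }
      xs <- c(xs, x); ys <- c(ys, y)
      break
    }
  }
  data.frame(x_m = xs, y_m = ys, sigma_m = sig, height_m = hgt)
}

# Lay n_fields rectangles on a regular grid of cells, inset from cell edges.
place_fields <- function(cfg, width_m, height_m) {
  if (cfg$n_fields == 0L) return(list())
  g <- ceiling(sqrt(cfg$n_fields))
  cw <- width_m / g; ch <- height_m / g
  fields <- vector("list", cfg$n_fields)
  for (i in seq_len(cfg$n_fields)) {
    cx <- (i - 1L) %% g; cy <- (i - 1L) %/% g
    x0 <- cfg$origin_xy[1] + cx * cw + 0.30 * cw
    x1 <- cfg$origin_xy[1] + (cx + 1) * cw - 0.30 * cw
    y0 <- cfg$origin_xy[2] - cy * ch - 0.30 * ch
    y1 <- cfg$origin_xy[2] - (cy + 1) * ch + 0.30 * ch
    fields[[i]] <- field_polygon(
      field_id = sprintf("F%03d", i),
      crop = c("maize", "millet", "peanut", "cotton",
               "soybean")[(i - 1L) %% 5L + 1L],
      ring = rbind(c(x0, y1), c(x1, y1), c(x1, y0), c(x0, y0)))
  }
  fields
}

# Grow connected cloud patches from random seed pixels until exactly
# `target` pixels are covered. Returns a logical matrix.
grow_cloud_patches <- function(nr, nc, target) {
  cl <- matrix(FALSE, nr, nc)
  if (target <= 0) return(cl)
  n_seeds <- max(1L, round(target / 400))
  seeds <- sample.int(nr * nc, n_seeds)
  cl[seeds] <- TRUE
  while (sum(cl) < target) {
    idx <- which(cl)
    r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
    nb <- rbind(cbind(r - 1L, c), cbind(r + 1L, c),
                cbind(r, c - 1L), cbind(r, c + 1L))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= nr & nb[, 2] >= 1 & nb[, 2] <= nc, ,
             drop = FALSE]
    cand <- unique(nb[, 1] + (nb[, 2] - 1L) * nr)
    cand <- cand[!cl[cand]]
    if (length(cand) == 0L) {             # patches saturated; reseed
      cand <- sample(which(!cl), 1L)
    }
    need <- target - sum(cl)
    take <- if (length(cand) > need) sample(cand, need) else cand
    cl[take] <- TRUE
  }
  cl
}

#' Generate a synthetic scene with ground truth
#'
#' Renders crop parcels, Gaussian tree crowns, sensor noise and cloud
#' patches per the configuration, returning the scene, its acquisition
#' metadata, and a ground-truth record of everything injected. Identical
#' configurations (including seeds) give bit-identical output.
#'
#' @param cfg a [sim_config()].
#' @return `list(scene, metadata, truth)` where `truth` has `crowns`
#'   (data frame x_m, y_m, sigma_m, height_m), `cloud_pixels` (linear,
#'   column-major pixel indices), `true_shift_xy_m`, `field_polygons`.
#' @export
simulate_scene <- function(cfg) {
  stopifnot(inherits(cfg, "ps_sim_config"))
  nr <- cfg$height_px; nc <- cfg$width_px
  width_m <- nc * cfg$gsd_m; height_m <- nr * cfg$gsd_m
  roles <- cfg$bands
  soil <- .SIM_SOIL[roles]

  layout <- with_seed(cfg$seed, {
    fields <- place_fields(cfg, width_m, height_m)
    crowns <- place_crowns(cfg, width_m, height_m, fields)
    ffac <- stats::runif(max(cfg$n_fields, 1L), 0.75, 1.25)
    cloud <- grow_cloud_patches(nr, nc, round(cfg$cloud_fraction * nr * nc))
    list(crowns = crowns, fields = fields, ffac = ffac, cloud = cloud)
  })

  bands <- lapply(roles, function(role) matrix(soil[[role]], nr, nc))
  names(bands) <- roles

  # parcels: homogeneous per-band reflectance, per-field brightness factor
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  cx <- cfg$origin_xy[1] + (cols - 0.5) * cfg$gsd_m
  cy <- cfg$origin_xy[2] - (rows - 0.5) * cfg$gsd_m
  for (i in seq_along(layout$fields)) {
    f <- layout$fields[[i]]
    inside <- matrix(points_in_polygon(as.vector(cx), as.vector(cy), f$ring),
                     nr, nc)
    for (role in roles) {
      v <- min(max(cfg$field_reflectance[[role]] * layout$ffac[i], 0), 1)
      bands[[role]][inside] <- v
    }
  }

  # crowns: additive isotropic Gaussians on nir1, green (and pan if present)
  crown_bands <- intersect(c("nir1", "green", "pan"), roles)
  if (nrow(layout$crowns)) {
    for (k in seq_len(nrow(layout$crowns))) {
      cr <- layout$crowns[k, ]
      rad <- 4 * cr$sigma_m
      r0 <- max(1L, floor((cfg$origin_xy[2] - cr$y_m - rad) / cfg$gsd_m))
      r1 <- min(nr, ceiling((cfg$origin_xy[2] - cr$y_m + rad) / cfg$gsd_m))
      c0 <- max(1L, floor((cr$x_m - cfg$origin_xy[1] - rad) / cfg$gsd_m))
      c1 <- min(nc, ceiling((cr$x_m - cfg$origin_xy[1] + rad) / cfg$gsd_m))
      if (r0 > r1 || c0 > c1) next
      rs <- r0:r1; cs <- c0:c1
      px <- cfg$origin_xy[1] + (cs - 0.5) * cfg$gsd_m
      py <- cfg$origin_xy[2] - (rs - 0.5) * cfg$gsd_m
      d2 <- outer((py - cr$y_m)^2, (px - cr$x_m)^2, `+`)
      bump <- cfg$crown_amplitude * exp(-d2 / (2 * cr$sigma_m^2))
      for (role in crown_bands)
        bands[[role]][rs, cs] <- bands[[role]][rs, cs] + bump
    }
  }

  # sensor noise (separate stream so repeat acquisitions differ only here)
  bands <- with_seed(cfg$noise_seed, {
    lapply(bands, function(b) {
      b <- b + stats::rnorm(length(b), sd = cfg$noise_sd)
      b[b < 0] <- 0; b[b > 1] <- 1
      b
    })
  })

  # clouds override everything: blue strictly above all background values
  cloud <- layout$cloud
  n_cloud <- sum(cloud)
  if (n_cloud > 0) {
    bands <- with_seed(cfg$noise_seed + 1L, {
      for (role in roles) {
        bg_max <- max(bands[[role]][!cloud])
        lo <- min(bg_max + 0.02, 0.98)
        hi <- min(bg_max + 0.10, 1)
        bands[[role]][cloud] <- stats::runif(n_cloud, lo, hi)
      }
      bands
    })
  }

  sc <- scene(bands, geotransform = c(cfg$origin_xy, cfg$gsd_m, cfg$gsd_m),
              crs_id = "EPSG:32630",
              scene_id = sprintf("SYN%06d", cfg$seed %% 1000000L))
  meta <- scene_metadata(
    scene_id = sc$scene_id,
    acquisition_time = as.POSIXct("2015-05-18 10:46:00", tz = "UTC") +
      (cfg$noise_seed %% 365L) * 86400,
    sun_elevation_deg = cfg$sun_elevation_deg,
    sun_azimuth_deg = cfg$sun_azimuth_deg,
    sat_offnadir_deg = cfg$sat_offnadir_deg,
    sat_azimuth_deg = cfg$sat_azimuth_deg,
    cloud_cover_pct = 100 * n_cloud / (nr * nc),
    sensor = "synthetic")
  truth <- list(crowns = layout$crowns,
                cloud_pixels = which(cloud),
                true_shift_xy_m = cfg$shift_xy_m,
                field_polygons = layout$fields)
  list(scene = sc, metadata = meta, truth = truth)
}

#' Simulate a multi-temporal site on disk
#'
#' Writes `n_scenes` repeat acquisitions of one synthetic landscape (same
#' parcels and trees, fresh sensor noise, per-scene misregistration
#' shifts, varying sun/sensor geometry) plus the field polygons, ready for
#' the incremental pipeline. Scene 1 is unshifted.
#'
#' @param out_dir output directory (created if absent).
#' @param n_scenes number of acquisitions.
#' @param base_cfg a [sim_config()]; its seed fixes the landscape.
#' @param max_shift_m per-axis magnitude bound of the random inter-scene
#'   shifts, metres.
#' @return list with `scenes` (per scene: `scene_id`, `raster`,
#'   `metadata` paths and `true_shift_xy_m`) and `fields_path`.
#' @export
simulate_site <- function(out_dir, n_scenes = 3L, base_cfg = sim_config(),
                          max_shift_m = 8) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  shifts <- with_seed(base_cfg$seed + 77L, {
    s <- matrix(stats::runif(2L * n_scenes, -max_shift_m, max_shift_m),
                ncol = 2)
    s[1, ] <- 0
    s
  })
  sun <- with_seed(base_cfg$seed + 78L,
                   stats::runif(n_scenes, 35, 75))
  scenes <- vector("list", n_scenes)
  fields_path <- file.path(out_dir, "fields.geojson")
  for (i in seq_len(n_scenes)) {
    cfg_i <- base_cfg
    cfg_i$noise_seed <- base_cfg$seed + 1000L * i
    cfg_i$shift_xy_m <- shifts[i, ]
    cfg_i$sun_elevation_deg <- sun[i]
    sim <- simulate_scene(cfg_i)
    sc <- sim$scene
    sc$scene_id <- sprintf("%s_T%02d", sc$scene_id, i)
    sim$metadata$scene_id <- sc$scene_id
    sim$metadata$acquisition_time <- sim$metadata$acquisition_time +
      i * 16 * 86400
    if (any(shifts[i, ] != 0))
      sc <- shift_scene(sc, shifts[i, ], "bilinear")
    raster <- file.path(out_dir, paste0(sc$scene_id, ".tif"))
    meta <- file.path(out_dir, paste0(sc$scene_id, ".meta.json"))
    write_scene(sc, raster)
    write_scene_metadata(sim$metadata, meta)
    if (i == 1L)
      write_fields_geojson(sim$truth$field_polygons, fields_path,
                           crs_id = sc$crs_id)
    scenes[[i]] <- list(scene_id = sc$scene_id, raster = raster,
                        metadata = meta,
                        true_shift_xy_m = shifts[i, ])
  }
  list(scenes = scenes, fields_path = fields_path)
}

#' Translate scene content by a map-metre shift
#'
#' The geotransform is unchanged; ground features move by `shift_xy_m`
#' (value at map coordinate p is taken from the source at p - shift).
#' Integer-pixel shifts under nearest-neighbour resampling are lossless in
#' the interior; pixels whose source falls outside the scene become nodata.
#'
#' @param scene a `ps_scene`.
#' @param shift_xy_m numeric length-2 (dx, dy) metres, |shift| smaller than
#'   the scene extent.
#' @param resampling `"nearest"` or `"bilinear"`.
#' @return the shifted `ps_scene`.
#' @export
shift_scene <- function(scene, shift_xy_m,
                        resampling = c("nearest", "bilinear")) {
  resampling <- match.arg(resampling)
  d <- scene_dim(scene)
  ext <- c(d[2] * scene$geotransform[3], d[1] * scene$geotransform[4])
  if (abs(shift_xy_m[1]) >= ext[1] || abs(shift_xy_m[2]) >= ext[2])
    stop("shift exceeds the scene extent")
  if (all(shift_xy_m == 0) && resampling == "nearest") return(scene)
  resample_scene(scene,
                 function(xy) cbind(xy[, 1] - shift_xy_m[1],
                                    xy[, 2] - shift_xy_m[2]),
                 resampling)
}
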