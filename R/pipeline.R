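# Make-like incremental pipeline driver.
#
# Each scene expands into a fixed stage chain (register onto the master,
# cloud mask, tree mask, field statistics) whose nodes carry content
# fingerprints: the md5 of input files, canonicalized parameters, and the
# parents' fingerprints. A node is stale when its stored fingerprint
# differs or its output is missing; staleness is closed under descendants.
# Fingerprints, not timestamps, drive re-execution, so copying or touching
# files does not trigger rebuilds.

md5_of_string <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}

md5_of_files <- function(paths) {
  ok <- file.exists(paths)
  h <- rep("ABSENT", length(paths))
  h[ok] <- unname(tools::md5sum(paths[ok]))
  h
}

canonical_params <- function(p) {
  jsonlite::toJSON(p, auto_unbox = TRUE, digits = 12, force = TRUE)
}

#' Pipeline run configuration
#'
#' @param scenes list of per-scene entries `list(scene_id, raster,
#'   metadata)` (as produced by [simulate_site()]).
#' @param fields_path GeoJSON path of the farm-field polygons.
#' @param out_dir directory for all stage outputs and the state file.
#' @param master `"auto"` (shadow-length master selection) or a scene id.
#' @param seed integer seed forwarded to the consensus estimator.
#' @param detector a [detector_config()].
#' @param tree a [tree_mask_config()].
#' @param vi a [vi_params()].
#' @param buffer_m field boundary buffer, metres.
#' @param distance_px co-occurrence displacement, pixels.
#' @param search_radius_m tie-point search radius, metres.
#' @param inlier_tol_m consensus inlier tolerance, metres.
#' @param model correction model, `"translation"` or `"affine"`.
#' @param mask_min_response blob response floor for tree masking.
#' @param resampling resampling kernel for the corrected scenes.
#' @return a `ps_run_config`.
#' @export
run_config <- function(scenes, fields_path, out_dir, master = "auto",
                       seed = 1L, detector = detector_config(),
                       tree = tree_mask_config(), vi = vi_params(),
                       buffer_m = 2, distance_px = 1L,
                       search_radius_m = 30, inlier_tol_m = 3,
                       model = "translation", mask_min_response = 0.04,
                       resampling = "bilinear") {
  if (length(scenes) == 0L) stop("no scenes configured")
  for (s in scenes)
    if (!all(c("scene_id", "raster", "metadata") %in% names(s)))
      stop("each scene needs scene_id, raster, metadata")
  if (!file.exists(fields_path)) stop("fields file not found: ", fields_path)
  structure(list(scenes = scenes, fields_path = fields_path,
                 out_dir = out_dir, master = master, seed = as.integer(seed),
                 detector = detector, tree = tree, vi = vi,
                 buffer_m = buffer_m, distance_px = as.integer(distance_px),
                 search_radius_m = search_radius_m,
                 inlier_tol_m = inlier_tol_m, model = model,
                 mask_min_response = mask_min_response,
                 resampling = resampling),
            class = "ps_run_config")
}

resolve_master <- function(config) {
  if (!identical(config$master, "auto")) return(config$master)
  metas <- lapply(config$scenes, function(s) read_scene_metadata(s$metadata))
  select_master(metas)
}

pipeline_paths <- function(config, scene_id) {
  od <- config$out_dir
  list(registered = file.path(od, paste0(scene_id, ".registered.tif")),
       correction = file.path(od, paste0(scene_id, ".correction.json")),
       cloud = file.path(od, paste0(scene_id, ".cloudmask.tif")),
       tree = file.path(od, paste0(scene_id, ".treemask.tif")),
       spectral = file.path(od, paste0(scene_id, ".spectral.csv")),
       texture = file.path(od, paste0(scene_id, ".texture.csv")))
}

state_path <- function(config) file.path(config$out_dir,
                                         "pipeline_state.json")

read_pipeline_state <- function(path) {
  if (!file.exists(path)) return(list())
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Build the incremental execution plan
#'
#' Expands the configured scenes into the stage graph, fingerprints every
#' node from its current inputs, parameters and parent fingerprints, and
#' marks as stale every node whose fingerprint differs from the recorded
#' state or whose outputs are absent, closing the stale set under
#' descendants.
#'
#' @param config a [run_config()].
#' @param state previously recorded fingerprints (defaults to the state
#'   file in `out_dir`).
#' @return a `ps_pipeline_plan`: data frame of nodes (`name`, `stage`,
#'   `scene_id`, `fingerprint`, `stale`), edge list, and the resolved
#'   master id.
#' @export
pipeline_plan <- function(config,
                          state = read_pipeline_state(state_path(config))) {
  stopifnot(inherits(config, "ps_run_config"))
  master_id <- resolve_master(config)
  if (!master_id %in% vapply(config$scenes, `[[`, "", "scene_id"))
    stop("master scene '", master_id, "' is not among the configured scenes")
  master_entry <- Filter(function(s) s$scene_id == master_id,
                         config$scenes)[[1]]
  reg_par <- list(detector = unclass(config$detector),
                  search_radius_m = config$search_radius_m,
                  inlier_tol_m = config$inlier_tol_m, model = config$model,
                  resampling = config$resampling, seed = config$seed)
  tree_par <- list(detector = unclass(config$detector),
                   tree = unclass(config$tree),
                   mask_min_response = config$mask_min_response)
  stats_par <- list(vi = unclass(config$vi), buffer_m = config$buffer_m,
                    distance_px = config$distance_px)
  nodes <- list(); edges <- list()
  add_node <- function(name, stage, scene_id, inputs, params, parents,
                       outputs) {
    nodes[[name]] <<- list(name = name, stage = stage, scene_id = scene_id,
                           inputs = inputs, params = params,
                           parents = parents, outputs = outputs)
    for (p in parents) edges[[length(edges) + 1L]] <<- c(p, name)
  }
  for (s in config$scenes) {
    id <- s$scene_id
    p <- pipeline_paths(config, id)
    reg_name <- paste0("register:", id)
    add_node(reg_name, "register", id,
             inputs = c(s$raster, s$metadata, master_entry$raster,
                        master_entry$metadata),
             params = c(reg_par, list(is_master = id == master_id)),
             parents = character(0),
             outputs = c(p$registered, p$correction))
    add_node(paste0("cloudmask:", id), "cloudmask", id,
             inputs = s$metadata, params = list(),
             parents = reg_name, outputs = p$cloud)
    add_node(paste0("treemask:", id), "treemask", id,
             inputs = s$metadata, params = tree_par,
             parents = paste0("register:", master_id), outputs = p$tree)
    add_node(paste0("stats:", id), "stats", id,
             inputs = c(s$metadata, config$fields_path),
             params = stats_par,
             parents = c(reg_name, paste0("cloudmask:", id),
                         paste0("treemask:", id)),
             outputs = c(p$spectral, p$texture))
  }
  order <- topo_order(names(nodes), edges)
  fps <- character(0)
  for (nm in order) {
    nd <- nodes[[nm]]
    fp <- md5_of_string(paste(c(md5_of_files(nd$inputs),
                                canonical_params(nd$params),
                                fps[nd$parents]), collapse = "|"))
    fps[nm] <- fp
    nodes[[nm]]$fingerprint <- fp
  }
  stale <- vapply(order, function(nm) {
    nd <- nodes[[nm]]
    !identical(unname(fps[nm]), state[[nm]]) || !all(file.exists(nd$outputs))
  }, TRUE)
  names(stale) <- order
  # close under descendants
  repeat {
    grew <- FALSE
    for (e in edges) if (stale[[e[1]]] && !stale[[e[2]]]) {
      stale[[e[2]]] <- TRUE; grew <- TRUE
    }
    if (!grew) break
  }
  structure(list(nodes = nodes[order], edges = edges,
                 order = order, stale = names(stale)[stale],
                 master_id = master_id),
            class = "ps_pipeline_plan")
}

topo_order <- function(names, edges) {
  indeg <- stats::setNames(integer(length(names)), names)
  for (e in edges) indeg[[e[2]]] <- indeg[[e[2]]] + 1L
  out <- character(0)
  ready <- names[indeg == 0L]
  while (length(ready)) {
    n <- ready[1]; ready <- ready[-1]
    out <- c(out, n)
    for (e in edges) if (e[1] == n) {
      indeg[[e[2]]] <- indeg[[e[2]]] - 1L
      if (indeg[[e[2]]] == 0L) ready <- c(ready, e[2])
    }
  }
  if (length(out) != length(names)) stop("internal error: cyclic plan")
  out
}

#' @export
print.ps_pipeline_plan <- function(x, ...) {
  cat(sprintf("<ps_pipeline_plan> %d nodes, %d stale (master %s)\n",
              length(x$nodes), length(x$stale), x$master_id))
  if (length(x$stale)) cat("  stale:", paste(x$stale, collapse = ", "), "\n")
  invisible(x)
}

run_stage <- function(stage, scene_id, config, master_id) {
  entry <- Filter(function(s) s$scene_id == scene_id, config$scenes)[[1]]
  master_entry <- Filter(function(s) s$scene_id == master_id,
                         config$scenes)[[1]]
  p <- pipeline_paths(config, scene_id)
  if (stage == "register") {
    tgt <- read_scene(entry$raster)
    tgt_meta <- read_scene_metadata(entry$metadata)
    if (scene_id == master_id) {
      write_scene(tgt, p$registered)
      corr <- list(model = "identity", parameters = list(tx = 0, ty = 0),
                   rmse_x_m = 0, rmse_y_m = 0, n_inliers = NA)
    } else {
      mst <- read_scene(master_entry$raster)
      mst_meta <- read_scene_metadata(master_entry$metadata)
      reg <- register_scene(mst, tgt, mst_meta, tgt_meta,
                            cfg = config$detector, model = config$model,
                            search_radius_m = config$search_radius_m,
                            inlier_tol_m = config$inlier_tol_m,
                            resampling = config$resampling,
                            seed = config$seed)
      write_scene(reg$scene, p$registered)
      corr <- list(model = reg$correction$model,
                   parameters = as.list(reg$correction$parameters),
                   rmse_x_m = reg$correction$rmse_x_m,
                   rmse_y_m = reg$correction$rmse_y_m,
                   n_inliers = reg$correction$n_inliers)
    }
    jsonlite::write_json(corr, p$correction, auto_unbox = TRUE, digits = NA)
  } else if (stage == "cloudmask") {
    sc <- read_scene(p$registered)
    meta <- read_scene_metadata(entry$metadata)
    write_mask(cloud_mask(sc, meta), p$cloud)
  } else if (stage == "treemask") {
    mst <- read_scene(pipeline_paths(config, master_id)$registered)
    blobs <- strong_blobs(detect_blobs(mst, "nir1", config$detector),
                          config$mask_min_response)
    mmask <- tree_mask_master(mst, blobs, config$tree)
    meta <- read_scene_metadata(entry$metadata)
    write_mask(adapt_tree_mask(mmask, meta, config$tree), p$tree)
  } else if (stage == "stats") {
    sc <- read_scene(p$registered)
    meta <- read_scene_metadata(entry$metadata)
    fields <- read_fields_geojson(config$fields_path)
    masks <- list(read_mask(p$cloud), read_mask(p$tree))
    ex <- extract_all(sc, meta, fields, masks, buffer_m = config$buffer_m,
                      params = config$vi, distance_px = config$distance_px)
    write_spectral_csv(ex$spectral, p$spectral)
    write_texture_csv(ex$texture, p$texture)
  } else stop("unknown stage: ", stage)
  invisible(NULL)
}

#' Execute the stale part of a pipeline plan
#'
#' Runs stale nodes in topological order, skipping descendants of any
#' failed stage, records updated fingerprints in the state file, and
#' writes a JSON report. Running an up-to-date plan executes zero stages;
#' an immediate second run is always a no-op.
#'
#' @param plan a [pipeline_plan()].
#' @param config the same [run_config()] the plan was built from.
#' @return the report: per-node `status` (`"up-to-date"`, `"run"`,
#'   `"failed"`, `"skipped"`), timings, counts, and `ok` (no failures).
#' @export
pipeline_run <- function(plan, config) {
  stopifnot(inherits(plan, "ps_pipeline_plan"),
            inherits(config, "ps_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- read_pipeline_state(state_path(config))
  status <- stats::setNames(rep("up-to-date", length(plan$order)),
                            plan$order)
  secs <- stats::setNames(rep(0, length(plan$order)), plan$order)
  failed_up <- character(0)
  for (nm in plan$order) {
    if (!nm %in% plan$stale) next
    nd <- plan$nodes[[nm]]
    if (any(nd$parents %in% failed_up)) {
      status[nm] <- "skipped"
      failed_up <- c(failed_up, nm)
      next
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      run_stage(nd$stage, nd$scene_id, config, plan$master_id)
      TRUE
    }, error = function(e) {
      message("stage ", nm, " failed: ", conditionMessage(e))
      FALSE
    })
    secs[nm] <- proc.time()[["elapsed"]] - t0
    if (res) {
      status[nm] <- "run"
      state[[nm]] <- unname(nd$fingerprint)
    } else {
      status[nm] <- "failed"
      failed_up <- c(failed_up, nm)
      state[[nm]] <- NULL
    }
  }
  jsonlite::write_json(state, state_path(config), auto_unbox = TRUE)
  report <- list(master_id = plan$master_id,
                 n_run = sum(status == "run"),
                 n_failed = sum(status == "failed"),
                 n_skipped = sum(status == "skipped"),
                 status = as.list(status),
                 seconds = as.list(round(secs, 3)),
                 seed = config$seed,
                 ok = !any(status %in% c("failed", "skipped")))
  jsonlite::write_json(report,
                       file.path(config$out_dir, "pipeline_report.json"),
                       auto_unbox = TRUE, digits = NA)
  report
}
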