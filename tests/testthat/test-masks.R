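test_that("zero cloud percentage and constant blue give empty masks", {
  s <- simulate_scene(sim_config(seed = 2))$scene
  expect_equal(sum(cloud_mask(s, test_meta(cloud_pct = 0))$grid), 0)
  s$bands$blue[] <- 0.3
  expect_equal(sum(cloud_mask(s, test_meta(cloud_pct = 10))$grid), 0)
})

test_that("the cloud mask recovers injected bright pixels exactly", {
  sim <- simulate_scene(sim_config(seed = 8, width_px = 100,
                                   height_px = 100, n_trees = 0,
                                   cloud_fraction = 0.1))
  m <- cloud_mask(sim$scene, sim$metadata)
  # sorting oracle: the p% brightest blue pixels
  blue <- sim$scene$bands$blue
  expected <- order(blue, decreasing = TRUE)[seq_len(1000)]
  expect_setequal(which(m$grid), expected)
  expect_setequal(which(m$grid), sim$truth$cloud_pixels)
})

test_that("the masked fraction never exceeds the metadata percentage", {
  for (seed in c(1, 4)) for (p in c(3, 12.5, 40)) {
    s <- simulate_scene(sim_config(seed = seed))$scene
    m <- cloud_mask(s, test_meta(cloud_pct = p))
    expect_lte(mean(m$grid), p / 100)
  }
})

test_that("nodata pixels are never cloud-masked", {
  s <- simulate_scene(sim_config(seed = 8, cloud_fraction = 0.05))
  sc <- s$scene
  sc$bands$blue[1:10, 1:10] <- NA_real_
  m <- cloud_mask(sc, s$metadata)
  expect_false(any(m$grid[1:10, 1:10]))
})

test_that("a single blob over vegetation masks the rasterized disc", {
  d <- 64L
  nir <- matrix(0.6, d, d); red <- matrix(0.15, d, d)   # NDVI = 0.6
  sc <- tiny_scene(nir); sc$bands$red <- red
  blob <- data.frame(x_m = 64, y_m = 1000 - 64, sigma_m = 6,
                     response = 0.1)
  m <- tree_mask_master(sc, blob, tree_mask_config(crown_radius_factor = 2))
  # disc oracle: pixel centres within 12 m of the centroid
  rows <- matrix(1:d, d, d); cols <- matrix(1:d, d, d, byrow = TRUE)
  cx <- (cols - 0.5) * 2; cy <- 1000 - (rows - 0.5) * 2
  disc <- (cx - 64)^2 + (cy - (1000 - 64))^2 <= 12^2
  expect_identical(m$grid, disc)
})

test_that("no blobs or bare soil give an empty tree mask", {
  sc <- tiny_scene(matrix(0.2, 32, 32))
  sc$bands$red <- matrix(0.19, 32, 32)            # NDVI ~ 0.026
  none <- tree_mask_master(sc, data.frame(x_m = numeric(0),
                                          y_m = numeric(0),
                                          sigma_m = numeric(0),
                                          response = numeric(0)))
  expect_equal(sum(none$grid), 0)
  blob <- data.frame(x_m = 32, y_m = 1000 - 32, sigma_m = 5, response = .1)
  expect_equal(sum(tree_mask_master(sc, blob)$grid), 0)
})

test_that("raising the NDVI threshold never adds tree-mask pixels", {
  s <- simulate_scene(sim_config(seed = 6))
  blobs <- strong_blobs(detect_blobs(s$scene))
  prev <- NULL
  for (thr in c(0.0, 0.2, 0.4, 0.6)) {
    m <- tree_mask_master(s$scene, blobs,
                          tree_mask_config(ndvi_threshold = thr))
    if (!is.null(prev)) expect_true(all(m$grid <= prev))
    prev <- m$grid
  }
})

test_that("tree-mask recall of crown cores reaches 95% at defaults", {
  hits <- 0L; tot <- 0L
  for (seed in c(3, 14)) {
    s <- simulate_scene(sim_config(seed = seed))
    m <- tree_mask_master(s$scene, strong_blobs(detect_blobs(s$scene)))
    gt <- s$scene$geotransform
    d <- dim(m$grid)
    rows <- matrix(seq_len(d[1]), d[1], d[2])
    cols <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
    cx <- gt[1] + (cols - 0.5) * gt[3]; cy <- gt[2] - (rows - 0.5) * gt[4]
    tr <- s$truth$crowns
    core <- matrix(FALSE, d[1], d[2])
    for (k in seq_len(nrow(tr)))
      core <- core | ((cx - tr$x_m[k])^2 + (cy - tr$y_m[k])^2 <=
                        tr$sigma_m[k]^2)
    hits <- hits + sum(m$grid & core); tot <- tot + sum(core)
  }
  expect_gte(hits / tot, 0.95)
})

test_that("mask adaptation shifts by h tan(offnadir) rounded to pixels", {
  g <- matrix(FALSE, 20, 20); g[10, 10] <- TRUE
  m <- mask_layer(g, "tree", "S", geotransform = c(0, 100, 2, 2))
  # off-nadir 0: identity
  a0 <- adapt_tree_mask(m, test_meta(offnadir = 0))
  expect_identical(a0$grid, g)
  # 10 m canopy, 20 deg off-nadir, azimuth east: 3.6397 m -> 2 columns
  a1 <- adapt_tree_mask(m, test_meta(offnadir = 20, sat_az = 90))
  expect_true(a1$grid[10, 12])
  expect_equal(sum(a1$grid), 1)
  # 45 deg, azimuth north: 10 m -> 5 rows up (north)
  a2 <- adapt_tree_mask(m, test_meta(offnadir = 45, sat_az = 0))
  expect_true(a2$grid[5, 10])
  expect_error(adapt_tree_mask(m, test_meta(offnadir = 90)), "90")
})

test_that("adaptation drops off-grid pixels and never grows the mask", {
  set.seed(31)
  g <- matrix(runif(400) < 0.3, 20, 20)
  m <- mask_layer(g, "tree", "S", geotransform = c(0, 100, 2, 2))
  a <- adapt_tree_mask(m, test_meta(offnadir = 45, sat_az = 270))
  expect_lte(sum(a$grid), sum(g))
})

test_that("combining masks is pixelwise OR", {
  set.seed(5)
  a <- matrix(runif(100) < 0.4, 10, 10)
  b <- matrix(runif(100) < 0.4, 10, 10)
  ma <- mask_layer(a, "cloud"); mb <- mask_layer(b, "tree")
  comb <- combine_masks(list(ma, mb))
  for (i in 1:10) for (j in 1:10)
    expect_identical(comb$grid[i, j], a[i, j] || b[i, j])
  expect_equal(comb$kind, "combined")
  expect_identical(combine_masks(list(ma)), ma)
  mc <- mask_layer(!a, "tree")
  expect_true(all(combine_masks(list(ma, mc))$grid))
  expect_error(combine_masks(list(ma, mask_layer(matrix(TRUE, 2, 2),
                                                 "tree"))),
               "dimensions")
})
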