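test_that("the lowest sun (longest shadow) wins master selection", {
  m30 <- test_meta("A", sun = 30)
  m60 <- test_meta("B", sun = 60)
  expect_equal(select_master(list(m60, m30)), "A")
  expect_equal(select_master(list(m60)), "B")
  expect_error(select_master(list()), "empty")
})

test_that("master-selection ties break by time then id", {
  a <- test_meta("B", sun = 45, time = "2015-05-01T10:00:00Z")
  b <- test_meta("A", sun = 45, time = "2015-06-01T10:00:00Z")
  expect_equal(select_master(list(a, b)), "B")   # earlier acquisition
  c2 <- test_meta("A", sun = 45, time = "2015-05-01T10:00:00Z")
  expect_equal(select_master(list(a, c2)), "A")  # same time: lexicographic
})

test_that("parallax adjustment moves centroids by h tan(offnadir)", {
  blobs <- data.frame(x_m = 100, y_m = 200, sigma_m = 5, response = 0.1)
  meta <- test_meta(offnadir = 20, sat_az = 90)
  adj <- parallax_adjust(blobs, meta, canopy_height_m = 10)
  expect_equal(adj$x_m, 100 - 10 * tan(20 * pi / 180))
  expect_equal(adj$y_m, 200, tolerance = 1e-9)
})

test_that("identical blob sets pair one-to-one with zero offset", {
  b <- data.frame(x_m = c(0, 50, 100), y_m = c(0, 40, 10),
                  sigma_m = c(4, 5, 6), response = c(0.1, 0.2, 0.3))
  pr <- match_tiepoints(b, b, search_radius_m = 20)
  expect_equal(nrow(pr), 3)
  expect_equal(pr$target_x_m - pr$master_x_m, rep(0, 3))
  expect_equal(sort(pr$match_score), sort(b$response))
})

test_that("a pure shift is recovered in every pair offset", {
  set.seed(42)
  g <- expand.grid(x = seq(0, 240, by = 60), y = seq(0, 120, by = 60))
  m <- data.frame(x_m = g$x + runif(15, -5, 5),
                  y_m = g$y + runif(15, -5, 5),
                  sigma_m = runif(15, 3, 8), response = runif(15, .05, .2))
  t <- m; t$x_m <- t$x_m + 12; t$y_m <- t$y_m - 6
  pr <- match_tiepoints(m, t, search_radius_m = 20)
  expect_equal(nrow(pr), 15)
  expect_equal(pr$target_x_m - pr$master_x_m, rep(12, 15))
  expect_equal(pr$target_y_m - pr$master_y_m, rep(-6, 15))
})

test_that("target blobs without a master within the radius stay unpaired", {
  m <- data.frame(x_m = 0, y_m = 0, sigma_m = 5, response = 0.1)
  t <- data.frame(x_m = c(1, 500), y_m = c(1, 500),
                  sigma_m = c(5, 5), response = c(0.1, 0.1))
  pr <- match_tiepoints(m, t, search_radius_m = 10)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$target_x_m, 1)
  expect_equal(nrow(match_tiepoints(m[0, ], t, 10)), 0)
})

test_that("exact pairs give the exact translation with zero RMSE", {
  p <- data.frame(master_x_m = runif(20, 0, 100),
                  master_y_m = runif(20, 0, 100))
  p$target_x_m <- p$master_x_m + 3.25
  p$target_y_m <- p$master_y_m - 1.50
  p$match_score <- runif(20, 0.05, 0.2)
  corr <- estimate_correction(p, "translation", inlier_tol_m = 1, seed = 7)
  expect_equal(unname(corr$parameters["tx"]), 3.25)
  expect_equal(unname(corr$parameters["ty"]), -1.50)
  expect_equal(corr$rmse_x_m, 0)
  expect_equal(corr$n_inliers, 20)
  # identical coordinates: zero translation
  q <- p; q$target_x_m <- q$master_x_m; q$target_y_m <- q$master_y_m
  c0 <- estimate_correction(q, "translation", inlier_tol_m = 1, seed = 7)
  expect_equal(unname(c0$parameters), c(0, 0))
})

test_that("gross outliers are excluded and leave the estimate unchanged", {
  set.seed(3)
  p <- data.frame(master_x_m = runif(20, 0, 100),
                  master_y_m = runif(20, 0, 100))
  p$target_x_m <- p$master_x_m + 3.25
  p$target_y_m <- p$master_y_m - 1.50
  p$match_score <- runif(20, 0.05, 0.2)
  out <- data.frame(master_x_m = runif(5, 0, 100),
                    master_y_m = runif(5, 0, 100))
  out$target_x_m <- out$master_x_m + 50
  out$target_y_m <- out$master_y_m + 50
  out$match_score <- runif(5, 0.05, 0.2)
  all <- rbind(p, out)[sample(25), ]
  corr <- estimate_correction(all, "translation", inlier_tol_m = 1,
                              seed = 5)
  expect_equal(corr$n_inliers, 20)
  expect_equal(unname(corr$parameters["tx"]), 3.25, tolerance = 1e-9)
  expect_equal(unname(corr$parameters["ty"]), -1.50, tolerance = 1e-9)
  # brute-force least squares on the known inlier set agrees
  expect_equal(unname(corr$parameters["tx"]),
               mean(p$target_x_m - p$master_x_m))
})

test_that("the estimate is invariant to pair ordering", {
  set.seed(8)
  p <- data.frame(master_x_m = runif(12, 0, 100),
                  master_y_m = runif(12, 0, 100))
  p$target_x_m <- p$master_x_m + 2 + rnorm(12, 0, 0.05)
  p$target_y_m <- p$master_y_m - 1 + rnorm(12, 0, 0.05)
  p$match_score <- runif(12, 0.05, 0.2)
  c1 <- estimate_correction(p, "translation", seed = 2)
  c2 <- estimate_correction(p[sample(12), ], "translation", seed = 2)
  expect_equal(c1$parameters, c2$parameters, tolerance = 1e-12)
})

test_that("affine fitting needs three non-collinear pairs", {
  p <- data.frame(master_x_m = c(0, 10, 20), master_y_m = c(0, 10, 20),
                  target_x_m = c(1, 11, 21), target_y_m = c(0, 10, 20),
                  match_score = 1)
  expect_error(estimate_correction(p[1:2, ], "affine"), "insufficient")
  expect_error(estimate_correction(p, "affine"), "consensus|degenerate")
  good <- data.frame(master_x_m = c(0, 10, 0, 10),
                     master_y_m = c(0, 0, 10, 10))
  good$target_x_m <- good$master_x_m + 5
  good$target_y_m <- good$master_y_m - 2
  good$match_score <- 1
  ca <- estimate_correction(good, "affine", inlier_tol_m = 1, seed = 1)
  expect_equal(unname(ca$parameters[c("a11", "a22")]), c(1, 1),
               tolerance = 1e-9)
  expect_equal(unname(ca$parameters[c("b1", "b2")]), c(-5, 2),
               tolerance = 1e-9)
})

test_that("identity correction returns the scene unchanged", {
  s <- simulate_scene(sim_config(seed = 10))$scene
  idc <- structure(list(model = "translation",
                        parameters = c(tx = 0, ty = 0)),
                   class = "ps_correction")
  expect_identical(apply_correction(s, idc, "nearest"), s)
})

test_that("applying an integer-pixel translation relocates pixels exactly", {
  s <- simulate_scene(sim_config(seed = 10))$scene
  sh <- shift_scene(s, c(4, 0), "nearest")       # content moved +2 px east
  corr <- structure(list(model = "translation",
                         parameters = c(tx = 4, ty = 0)),
                    class = "ps_correction")
  back <- apply_correction(sh, corr, "nearest")
  expect_equal(back$bands$red[, 3:126], s$bands$red[, 3:126])
})

test_that("half-pixel bilinear correction matches the ramp closed form", {
  d <- 32L
  ramp <- matrix(rep(seq(0, 1, length.out = d), each = d), d, d,
                 byrow = TRUE)
  sc <- tiny_scene(ramp, gsd = 1, origin = c(0, 100))
  corr <- structure(list(model = "translation",
                         parameters = c(tx = -0.5, ty = 0)),
                    class = "ps_correction")
  out <- apply_correction(sc, corr, "bilinear")
  expected <- (ramp[, 2:(d - 1)] + ramp[, 1:(d - 2)]) / 2
  expect_equal(out$bands$nir1[, 2:(d - 1)], expected, tolerance = 1e-12)
})

test_that("control-point statistics match the definition formulas", {
  pts <- matrix(runif(20), 10, 2)
  expect_equal(evaluate_against_controls(pts, pts),
               oracle_residual_stats(pts, pts))
  sp <- pts + matrix(rep(c(1, -2), each = 10), 10, 2)
  st <- evaluate_against_controls(sp, pts)
  expect_equal(st$mean_abs_dx, 1)
  expect_equal(st$sd_abs_dx, 0)
  expect_equal(st$rmse_x, 1)
  expect_equal(st$rmse_y, 2)
  set.seed(19)
  sp2 <- pts + matrix(rnorm(20, 0, 0.5), 10, 2)
  expect_equal(evaluate_against_controls(sp2, pts),
               oracle_residual_stats(sp2, pts), tolerance = 1e-12)
  expect_error(evaluate_against_controls(pts[1:3, ], pts), "length")
})
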