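sq_field <- function(side = 10, origin = c(0, 0), id = "F", crop = "maize")
  field_polygon(id, crop,
                rbind(origin, origin + c(side, 0), origin + c(side, side),
                      origin + c(0, side)))

test_that("negative buffering shrinks a square by the offset", {
  f <- sq_field(10)
  expect_identical(buffer_field(f, 0), f)
  b <- buffer_field(f, 2)
  expect_equal(abs(polygon_area <- (function(r) {
    n <- nrow(r); j <- c(n, 1:(n - 1))
    sum(r[j, 1] * r[, 2] - r[, 1] * r[j, 2]) / 2
  })(b$ring)), 36)
  expect_null(buffer_field(f, 5))
  expect_error(buffer_field(f, -1), "buffer_m")
})

test_that("pixel membership is centre-in-polygon on the buffered ring", {
  d <- 20L
  b <- matrix(0.3, d, d)
  sc <- scene(list(blue = b, green = b, red = b, nir1 = b),
              geotransform = c(0, 20, 1, 1), scene_id = "S")
  f <- buffer_field(sq_field(10, origin = c(2, 2)), 2)   # 6x6 m inner square
  px <- field_pixels(sc, f)
  expect_length(px$total, 36)
  expect_length(px$used, 36)
  allmask <- mask_layer(matrix(TRUE, d, d), "cloud")
  px2 <- field_pixels(sc, f, allmask)
  expect_length(px2$total, 36)
  expect_length(px2$used, 0)
  outside <- sq_field(5, origin = c(100, 100))
  px3 <- field_pixels(sc, outside)
  expect_length(px3$total, 0)
})

test_that("mask growth never increases the used pixel count", {
  s <- simulate_scene(sim_config(seed = 12))
  f <- buffer_field(s$truth$field_polygons[[1]], 2)
  set.seed(1)
  g1 <- matrix(runif(128 * 128) < 0.2, 128, 128)
  g2 <- g1 | (matrix(runif(128 * 128) < 0.2, 128, 128))
  n1 <- length(field_pixels(s$scene, f, mask_layer(g1, "cloud"))$used)
  n2 <- length(field_pixels(s$scene, f, mask_layer(g2, "cloud"))$used)
  expect_lte(n2, n1)
})

test_that("moments of a symmetric triple match the closed form", {
  m <- spectral_moments(list(b = c(0.1, 0.2, 0.3)))
  expect_equal(unname(m$mean), 0.2)
  expect_equal(unname(m$variance), 0.00666666667, tolerance = 1e-9)
  expect_equal(unname(m$skewness), 0, tolerance = 1e-9)
})

test_that("constant bands have zero variance and undefined skewness", {
  m <- spectral_moments(list(a = rep(0.4, 5), b = 1:5 / 10))
  expect_equal(unname(m$variance["a"]), 0)
  expect_true(is.na(m$skewness[["a"]]))
  expect_true(is.na(m$corr["a", "b"]))
  expect_equal(m$corr["b", "b"], 1)
})

test_that("moments and corr/cov match the definition oracle", {
  set.seed(77)
  for (rep in 1:5) {
    vals <- list(a = runif(1000), b = runif(1000)^2, c = rnorm(1000, .5, .1))
    got <- spectral_moments(vals)
    want <- oracle_moments(vals)
    expect_equal(got$mean, want$mean, tolerance = 1e-12)
    expect_equal(got$variance, want$variance, tolerance = 1e-12)
    expect_equal(got$skewness, want$skewness, tolerance = 1e-12)
    expect_equal(got$cov, want$cov, tolerance = 1e-12)
    expect_equal(got$corr, want$corr, tolerance = 1e-12)
  }
})

test_that("moment edge cases: empty input and ragged bands", {
  m <- spectral_moments(list(a = numeric(0), b = numeric(0)))
  expect_true(all(is.na(m$mean)))
  expect_equal(m$n, 0)
  expect_error(spectral_moments(list(a = 1:3 / 10, b = 1:4 / 10)),
               "unequal")
})

test_that("correlation matrices stay within [-1, 1] with unit diagonal", {
  set.seed(41)
  for (rep in 1:10) {
    vals <- list(a = runif(50), b = runif(50), c = runif(50))
    co <- spectral_moments(vals)$corr
    expect_true(all(abs(co) <= 1 + 1e-12, na.rm = TRUE))
    expect_equal(unname(diag(co)), rep(1, 3))
    expect_equal(co, t(co))
  }
})

test_that("vegetation indices evaluate their formulas exactly", {
  v <- vegetation_indices(list(nir1 = 0.5, red = 0.1, blue = 0.05,
                               green = 0.1, rededge = 0.2, nir2 = 0.4))
  expect_equal(v$ndvi, 0.4 / 0.6)
  expect_equal(v$evi, 2.5 * 0.4 / (0.5 + 0.6 - 0.375 + 1))
  expect_equal(v$sr, 5)
  expect_equal(v$gndvi, 0.4 / 0.6)
  expect_equal(v$savi, 1.5 * 0.4 / (0.5 + 0.1 + 0.5))
  rrb <- 0.1 - 1 * (0.05 - 0.1)
  expect_equal(v$sarvi, 1.5 * (0.5 - rrb) / (0.5 + rrb + 0.5))
  expect_equal(v$tcari,
               3 * ((0.2 - 0.1) - 0.2 * (0.2 - 0.1) * (0.2 / 0.1)))
  expect_equal(v$msavi2,
               (2 * 0.5 + 1 - sqrt((2 * 0.5 + 1)^2 - 8 * 0.4)) / 2)
  expect_equal(v$ndvi_nir2, 0.3 / 0.5)
})

test_that("equal NIR and red forces NDVI = MSAVI2 = 0 and ratio 1", {
  v <- vegetation_indices(list(nir1 = 0.3, red = 0.3, blue = 0.1,
                               green = 0.2))
  expect_equal(v$ndvi, 0)
  expect_equal(v$sr, 1)
  expect_equal(v$msavi2, 0)
})

test_that("indices needing absent bands are omitted, zero denominators NA", {
  v <- vegetation_indices(list(nir1 = 0.4, red = 0.2, blue = 0.1,
                               green = 0.15))
  expect_false("tcari" %in% names(v))
  expect_false("ndvi_nir2" %in% names(v))
  expect_true(all(c("ndvi", "evi", "savi") %in% names(v)))
  z <- vegetation_indices(list(nir1 = 0, red = 0, blue = 0, green = 0))
  expect_true(is.na(z$ndvi))
  expect_true(is.na(z$sr))
})

test_that("a field of two equal halves has the two-point mean and sd", {
  d <- 10L
  nir <- matrix(0, d, d); red <- matrix(0, d, d)
  nir[, 1:5] <- 0.45; red[, 1:5] <- 0.3    # NDVI 0.2
  nir[, 6:10] <- 0.4; red[, 6:10] <- 0.1   # NDVI 0.6
  sc <- scene(list(blue = matrix(.1, d, d), green = matrix(.1, d, d),
                   red = red, nir1 = nir),
              geotransform = c(0, 10, 1, 1), scene_id = "S")
  f <- sq_field(10)
  vs <- field_vi_summary(sc, f)
  expect_equal(vs$ndvi$mean, 0.4, tolerance = 1e-12)
  expect_equal(vs$ndvi$sd, 0.2, tolerance = 1e-12)
  # homogeneous field: sd 0 for every index
  sc2 <- sc; sc2$bands$nir1[] <- 0.4; sc2$bands$red[] <- 0.1
  vs2 <- field_vi_summary(sc2, f)
  for (nm in names(vs2)) expect_equal(vs2[[nm]]$sd, 0)
})

test_that("per-field statistics are invariant to pixel ordering", {
  set.seed(9)
  vals <- list(a = runif(100), b = runif(100))
  perm <- sample(100)
  m1 <- spectral_moments(vals)
  m2 <- spectral_moments(lapply(vals, function(v) v[perm]))
  expect_equal(m1, m2, tolerance = 1e-12)
})
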