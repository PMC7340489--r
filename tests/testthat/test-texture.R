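test_that("the 2x2 two-level grid gives the hand-enumerated GLCM", {
  lv <- matrix(c(0L, 1L, 0L, 1L), 2, 2)        # rows: (0,0) / (1,1)
  P <- glcm(lv, glcm_spec(2L, 0L))
  expect_equal(P, matrix(c(0.5, 0, 0, 0.5), 2, 2))
})

test_that("a constant grid concentrates all co-occurrence mass", {
  P <- glcm(matrix(0L, 5, 5), glcm_spec(4L, 0L))
  expect_equal(sum(P != 0), 1)
  expect_equal(P[1, 1], 1)
})

test_that("GLCM is normalized and symmetric for any input", {
  set.seed(23)
  for (ang in c(0L, 45L, 90L, 135L)) {
    lv <- matrix(sample(0:7, 100, TRUE), 10, 10)
    lv[sample(100, 20)] <- NA                   # irregular support
    P <- glcm(lv, glcm_spec(8L, ang))
    expect_equal(sum(P), 1, tolerance = 1e-12)
    expect_equal(P, t(P), tolerance = 1e-12)
    expect_equal(P, oracle_glcm(lv, 8L, ang), tolerance = 1e-12)
  }
})

test_that("degenerate fields are refused", {
  expect_error(glcm(matrix(NA_integer_, 3, 3), glcm_spec(4L, 0L)),
               "degenerate")
  lone <- matrix(NA_integer_, 3, 3); lone[2, 2] <- 1L
  expect_error(glcm(lone, glcm_spec(4L, 0L)), "degenerate")
  expect_error(glcm(matrix(9L, 2, 2), glcm_spec(4L, 0L)), "range")
})

test_that("the diagonal two-cell matrix gives the hand-derived descriptors", {
  P <- matrix(c(0.5, 0, 0, 0.5), 2, 2)
  h <- haralick(P)
  expect_equal(h$f_asm, 0.5)
  expect_equal(h$f_contrast, 0)
  expect_equal(h$f_entropy, 1)                 # one bit
  expect_equal(h$f_homogeneity, 1)
  expect_equal(h$f_max_corr_coeff, 1)
})

test_that("a point-mass matrix has ASM 1 and zero entropies", {
  P <- matrix(0, 3, 3); P[2, 2] <- 1
  h <- haralick(P)
  expect_equal(h$f_asm, 1)
  expect_equal(h$f_entropy, 0)
  expect_equal(h$f_sum_entropy, 0)
  expect_equal(h$f_diff_entropy, 0)
  expect_error(haralick(P * 2), "normalized")
})

test_that("all descriptors match the brute-force oracle on random matrices", {
  set.seed(65)
  for (rep in 1:8) {
    M <- matrix(runif(64), 8, 8)
    M <- M + t(M)
    P <- M / sum(M)
    got <- haralick(P)
    want <- oracle_haralick(P)
    for (nm in names(want))
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-10, label = nm)
  }
})

test_that("quantization stretches the field range into G levels", {
  v <- matrix(seq(0.2, 0.8, length.out = 16), 4, 4)
  q <- quantize_levels(v, 4L)
  expect_equal(range(q), c(0L, 3L))
  expect_equal(sort(unique(as.vector(q))), 0:3)
  const <- quantize_levels(matrix(0.5, 3, 3), 64L)
  expect_true(all(const == 0L))
  withna <- matrix(c(NA, 0.1, 0.9, NA), 2, 2)
  q2 <- quantize_levels(withna, 2L)
  expect_true(is.na(q2[1, 1]))
  expect_equal(q2[2, 1], 0L)
  expect_equal(q2[1, 2], 1L)
})

test_that("a checkerboard maximizes contrast at angle 0", {
  d <- 8L
  chk <- outer(1:d, 1:d, function(r, c) (r + c) %% 2) * 0.6 + 0.2
  G <- 64L
  lv <- quantize_levels(chk, G)
  P <- glcm(lv, glcm_spec(G, 0L))
  h <- haralick(P)
  expect_equal(h$f_contrast, (G - 1)^2)         # every pair spans the range
  expect_equal(h$f_homogeneity, 1 / (1 + (G - 1)^2))
})

test_that("rotating a pattern 90 deg swaps the 0 and 90 deg descriptors", {
  set.seed(3)
  v <- matrix(runif(64), 8, 8)
  lv <- quantize_levels(v, 16L)
  vr <- t(v)[, 8:1]                             # 90 deg rotation
  lvr <- quantize_levels(vr, 16L)
  h0 <- haralick(glcm(lv, glcm_spec(16L, 0L)))
  h90r <- haralick(glcm(lvr, glcm_spec(16L, 90L)))
  for (nm in names(h0))
    expect_equal(h0[[nm]], h90r[[nm]], tolerance = 1e-10, label = nm)
})

test_that("field_texture yields 8 records per field with sane values", {
  s <- simulate_scene(sim_config(seed = 4))
  f <- s$truth$field_polygons[[2]]
  recs <- field_texture(s$scene, buffer_field(f, 2))
  expect_length(recs, 8)
  gl <- vapply(recs, `[[`, 0, "grey_levels")
  ang <- vapply(recs, `[[`, 0, "angle_deg")
  expect_equal(sort(unique(gl)), c(64, 256))
  expect_equal(sort(unique(ang)), c(0, 45, 90, 135))
  for (r in recs) {
    expect_gt(r$f_asm, 0); expect_lte(r$f_asm, 1)
    expect_gte(r$f_entropy, 0)
    expect_gt(r$f_homogeneity, 0); expect_lte(r$f_homogeneity, 1)
  }
})

test_that("a constant field has ASM 1 in all eight records", {
  d <- 16L
  b <- matrix(0.5, d, d)
  sc <- scene(list(blue = b, green = b, red = b, nir1 = b,
                   pan = b),
              geotransform = c(0, 32, 2, 2), scene_id = "S")
  f <- field_polygon("F", "x", rbind(c(4, 4), c(28, 4), c(28, 28),
                                     c(4, 28)))
  recs <- field_texture(sc, f)
  for (r in recs) expect_equal(r$f_asm, 1)
})

test_that("an unusably small field yields NA descriptors, not an error", {
  d <- 16L
  b <- matrix(0.5, d, d)
  sc <- scene(list(blue = b, green = b, red = b, nir1 = b),
              geotransform = c(0, 32, 2, 2), scene_id = "S")
  f <- field_polygon("F", "x", rbind(c(2, 2), c(4.5, 2), c(4.5, 4.5),
                                     c(2, 4.5)))
  recs <- field_texture(sc, f, band_role = "nir1")
  expect_length(recs, 8)
  expect_true(all(is.na(vapply(recs, `[[`, 0, "f_asm"))))
})
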