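test_that("fixed-bin-width discretization follows the anchored-floor rule", {
  idx <- discretize(c(0, 15.9, 16, 47), bin_width = 16)
  expect_equal(as.integer(idx), c(1L, 1L, 2L, 3L))
  expect_equal(attr(idx, "n_levels"), 3L)

  const <- discretize(rep(80, 10), bin_width = 16)
  expect_true(all(const == 1L))
  expect_equal(attr(const, "n_levels"), 1L)

  expect_error(discretize(numeric(0)), class = "pancrad_empty_roi_error")

  set.seed(9)
  for (rep in 1:10) {
    v <- runif(200, -300, 300)
    idx <- discretize(v, 16)
    # brute-force recompute per element
    expect_equal(as.integer(idx), floor((v - min(v)) / 16) + 1)
    expect_lte(attr(idx, "n_levels"), ceiling((max(v) - min(v)) / 16) + 1)
  }
})

test_that("2x2 checkerboard has a zero-diagonal horizontal GLCM", {
  idx <- array(c(1L, 2L, 2L, 1L), c(2, 2, 1))
  tm <- build_texture_matrix(idx, "glcm", "2d", n_levels = 2)
  horiz <- tm$matrix[[1]]   # direction (1, 0)
  expect_equal(diag(horiz), c(0, 0))
  expect_equal(sum(horiz), 4)  # two pairs, symmetrized
})

test_that("GLCM on a worked 4x4 grid equals exhaustive pair enumeration", {
  set.seed(21)
  idx <- array(sample(1:3, 16, replace = TRUE), c(4, 4, 1))
  storage.mode(idx) <- "integer"
  tm <- build_texture_matrix(idx, "glcm", "2d", n_levels = 3)
  oracle <- oracle_glcm(idx, 3, threeD = FALSE)
  for (a in 1:4) expect_equal(unclass(tm$matrix[[a]]), oracle[[a]])
  # correlation from direct summation over matrix entries
  expect_equal(unname(compute_feature(tm, "glcm_correlation")),
               unname(oracle_glcm_feats(oracle)["correlation"]),
               tolerance = 1e-12)
})

test_that("degenerate regions take the documented fallback values", {
  const <- rep(55, 30)
  expect_equal(unname(compute_feature(const, "firstorder_median")), 55)
  expect_equal(unname(compute_feature(const, "firstorder_skewness")), 0)

  idx <- array(1L, c(3, 3, 1))   # single gray level -> zero variance
  tm <- build_texture_matrix(idx, "glcm", "2d", n_levels = 1)
  expect_equal(unname(compute_feature(tm, "glcm_correlation")), 1)

  one <- array(0L, c(3, 3, 1)); one[2, 2, 1] <- 1L   # single-voxel ROI
  ng <- build_texture_matrix(one, "ngtdm", "2d", n_levels = 1)
  expect_equal(sum(ng$matrix), 0)   # no valid neighbors: empty NGTDM
  expect_equal(unname(compute_feature(ng, "ngtdm_coarseness")), 1e6)

  expect_error(compute_feature(const, "firstorder_mode"),
               class = "pancrad_config_error")
})

test_that("every texture family equals its direct-summation oracle on small grids", {
  set.seed(77)
  cases <- list(list(d = c(6, 6, 1), threeD = FALSE, nlev = 4),
                list(d = c(5, 6, 1), threeD = FALSE, nlev = 3),
                list(d = c(6, 6, 3), threeD = TRUE, nlev = 4),
                list(d = c(4, 5, 3), threeD = TRUE, nlev = 5))
  for (cs in cases) {
    for (rep in 1:3) {
      idx <- random_index_array(cs$d, cs$nlev)
      if (sum(idx > 0) < 2) next
      dm <- if (cs$threeD) "3d" else "2d"
      n_vox <- sum(idx > 0)

      tm <- build_texture_matrix(idx, "glcm", dm, n_levels = cs$nlev)
      o <- oracle_glcm_feats(oracle_glcm(idx, cs$nlev, cs$threeD))
      for (f in names(o))
        expect_equal(unname(compute_feature(tm, paste0("glcm_", f))),
                     unname(o[f]), tolerance = 1e-8)

      tm <- build_texture_matrix(idx, "glrlm", dm, n_levels = cs$nlev)
      o <- oracle_glrlm_feats(oracle_glrlm(idx, cs$nlev, cs$threeD), n_vox)
      for (f in names(o))
        expect_equal(unname(compute_feature(tm, paste0("glrlm_", f))),
                     unname(o[f]), tolerance = 1e-8)

      tm <- build_texture_matrix(idx, "glszm", dm, n_levels = cs$nlev)
      o <- oracle_glszm_feats(oracle_glszm(idx, cs$nlev, cs$threeD), n_vox)
      for (f in names(o))
        expect_equal(unname(compute_feature(tm, paste0("glszm_", f))),
                     unname(o[f]), tolerance = 1e-8)

      tm <- build_texture_matrix(idx, "gldm", dm, n_levels = cs$nlev)
      o <- oracle_gldm_feats(oracle_gldm(idx, cs$nlev, cs$threeD))
      for (f in names(o))
        expect_equal(unname(compute_feature(tm, paste0("gldm_", f))),
                     unname(o[f]), tolerance = 1e-8)

      tm <- build_texture_matrix(idx, "ngtdm", dm, n_levels = cs$nlev)
      o <- oracle_ngtdm_feats(oracle_ngtdm(idx, cs$nlev, cs$threeD))
      for (f in names(o))
        expect_equal(unname(compute_feature(tm, paste0("ngtdm_", f))),
                     unname(o[f]), tolerance = 1e-8)
    }
  }
})

test_that("first-order features equal the direct formulas", {
  set.seed(31)
  for (rep in 1:5) {
    v <- round(runif(150, -100, 200))
    o <- oracle_firstorder(v)
    for (f in names(o))
      expect_equal(unname(compute_feature(v, paste0("firstorder_", f))),
                   unname(o[f]), tolerance = 1e-10)
  }
})

test_that("normalized texture matrices sum to one", {
  set.seed(13)
  idx <- random_index_array(c(6, 6, 3), 4)
  for (fam in c("glcm", "glrlm")) {
    tm <- build_texture_matrix(idx, fam, "3d", n_levels = 4)
    for (m in tm$matrix) {
      if (sum(m) == 0) next
      expect_equal(sum(m / sum(m)), 1, tolerance = 1e-9)
    }
  }
  for (fam in c("glszm", "gldm")) {
    tm <- build_texture_matrix(idx, fam, "3d", n_levels = 4)
    expect_equal(sum(tm$matrix / sum(tm$matrix)), 1, tolerance = 1e-9)
  }
})

test_that("texture features are invariant to a constant HU shift", {
  set.seed(8)
  vox <- array(round(rnorm(10 * 10 * 3, 100, 30)), c(10, 10, 3))
  roi <- array(TRUE, c(10, 10, 3))
  manifest <- feature_manifest("original",
                               c("glcm_contrast", "ngtdm_busyness",
                                 "glszm_large_area_emphasis",
                                 "gldm_dependence_entropy",
                                 "glrlm_long_run_emphasis"))
  a <- extract_from_images(list(original = vox), roi, manifest)
  b <- extract_from_images(list(original = vox + 500), roi, manifest)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("wavelet bands split lowpass/highpass content as expected", {
  const <- matrix(7, 16, 16)
  b <- wavelet_bands(const)
  expect_named(b, c("LL", "HL", "LH", "HH"))
  expect_equal(max(abs(b$LL - b$LL[1, 1])), 0, tolerance = 1e-9)
  expect_lt(max(abs(b$HH)), 1e-9)
  expect_lt(max(abs(b$HL)), 1e-9)

  # LL-only reconstruction of a smooth ramp approximates the input
  ramp <- outer(seq(0, 1, length.out = 32), seq(0, 1, length.out = 32), `+`)
  rec <- pancrad:::wavelet_reconstruct_ll(wavelet_bands(ramp)$LL)
  interior <- 5:28
  expect_lt(max(abs(rec[interior, interior] - ramp[interior, interior])),
            0.01)

  b3 <- wavelet_bands(array(1, c(8, 8, 4)))
  expect_length(b3, 8)
  expect_named(b3, c("LLL", "HLL", "LHL", "HHL", "LLH", "HLH", "LHH",
                     "HHH"))
})

test_that("LoG impulse response matches the analytic kernel", {
  d <- c(25, 25, 9)
  imp <- array(0, d)
  imp[13, 13, 5] <- 1
  sp <- c(1, 1, 5)
  out <- log_filter(imp, sigma_mm = 3, spacing = sp)
  offs <- expand.grid(x = -3:3, y = -3:3, z = -1:1)
  expected <- pancrad:::log_kernel_analytic(
    cbind(offs$x * sp[1], offs$y * sp[2], offs$z * sp[3]), 3) * prod(sp)
  got <- mapply(function(x, y, z) out[13 + x, 13 + y, 5 + z],
                offs$x, offs$y, offs$z)
  expect_equal(got, expected, tolerance = 1e-8)
})

test_that("feature vectors are deterministic and manifest-driven", {
  st <- generate_phantom_study(phantom_spec(), TRUE, 99L)
  roi <- roi_union(st$mask)
  man <- feature_manifest(c("original", "wavelet-LLL"),
                          c("firstorder_mean", "glcm_imc2"))
  expect_equal(nrow(man), 4)
  a <- extract_feature_vector(st$volume, roi, manifest = man)
  b <- extract_feature_vector(st$volume, roi, manifest = man)
  expect_identical(a, b)
  expect_equal(names(a), man$name)

  man3 <- feature_manifest("original", c("firstorder_mean",
                                         "firstorder_median",
                                         "ngtdm_coarseness"))
  expect_length(extract_feature_vector(st$volume, roi, manifest = man3), 3)
  expect_error(feature_manifest("original", "glcm_bogus"),
               class = "pancrad_config_error")
})

test_that("tumor patches are busier and darker than pancreas patches", {
  spec <- phantom_spec()
  man <- feature_manifest("original", c("ngtdm_busyness",
                                        "firstorder_median"))
  tum <- NULL
  pan <- NULL
  k <- 0
  n_rows <- function(m) if (is.null(m)) 0L else nrow(m)
  while ((n_rows(tum) < 100 || n_rows(pan) < 100) && k < 12) {
    k <- k + 1
    st <- generate_phantom_study(spec, TRUE, 3000L + k)
    ps <- label_patches(generate_patches(roi_union(st$mask)), st$mask)
    x <- study_patch_features(st$volume, st$mask, ps, manifest = man)
    lab <- ps$patches$label
    tum <- rbind(tum, x[lab == "cancerous", , drop = FALSE])
    pan <- rbind(pan, x[lab == "non-cancerous", , drop = FALSE])
  }
  expect_gte(nrow(tum), 100)
  expect_gte(nrow(pan), 100)
  # directions reported for the top 2D features: busyness up, median down
  expect_gt(median(tum[, "original_ngtdm_busyness"]),
            median(pan[, "original_ngtdm_busyness"]))
  expect_lt(median(tum[, "original_firstorder_median"]),
            median(pan[, "original_firstorder_median"]))
})
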