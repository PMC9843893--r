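scored_patchset <- function(dim3, rows) {
  roi <- array(1L, dim3)
  ps <- generate_patches(label_mask(roi, c(1, 1, 5)))
  keep <- merge(ps$patches, rows, by = c("slice", "x0", "y0"))
  ps$patches <- keep[order(keep$slice, keep$y0, keep$x0), ]
  ps
}

test_that("heatmap pixels average the probabilities of covering patches", {
  ps <- scored_patchset(c(40, 40, 1),
                        data.frame(slice = 0, x0 = 0, y0 = 0,
                                   probability = 0.8))
  h <- build_heatmap(ps)
  expect_equal(sum(!is.na(h$values)), 400)
  expect_true(all(h$values[1:20, 1:20, 1] == 0.8))
  expect_equal(max(h$coverage), 1)

  ps2 <- scored_patchset(c(40, 40, 1),
                         data.frame(slice = 0, x0 = c(0, 10), y0 = 0,
                                    probability = c(0.2, 0.6)))
  h2 <- build_heatmap(ps2)
  expect_true(all(h2$values[11:20, 1:20, 1] == 0.4))  # overlap: mean
  expect_true(all(h2$values[1:10, 1:20, 1] == 0.2))
  expect_true(all(h2$values[21:30, 1:20, 1] == 0.6))
})

test_that("random layouts equal a brute-force accumulation oracle", {
  set.seed(12)
  st <- generate_phantom_study(phantom_spec(), TRUE, 7L)
  ps <- generate_patches(roi_union(st$mask))
  ps$patches$probability <- runif(nrow(ps$patches))
  h <- build_heatmap(ps)
  acc <- array(0, ps$dim)
  cnt <- array(0L, ps$dim)
  p <- ps$patches
  for (r in seq_len(nrow(p))) {
    xs <- p$x0[r] + 1:20; ys <- p$y0[r] + 1:20; z <- p$slice[r] + 1
    acc[xs, ys, z] <- acc[xs, ys, z] + p$probability[r]
    cnt[xs, ys, z] <- cnt[xs, ys, z] + 1L
  }
  expect_equal(h$values[cnt > 0], (acc / cnt)[cnt > 0], tolerance = 1e-12)
  expect_true(all(is.na(h$values[cnt == 0])))
  # order invariance
  ps_shuf <- ps
  ord <- sample(nrow(p))
  ps_shuf$patches <- p[ord, ]
  expect_equal(build_heatmap(ps_shuf)$values, h$values)
})

test_that("unscored patches are a state error", {
  st <- generate_phantom_study(phantom_spec(), FALSE, 5L)
  ps <- generate_patches(roi_union(st$mask))
  expect_error(build_heatmap(ps), class = "pancrad_state_error")
})

test_that("largest high-risk area picks the biggest in-plane component", {
  vals <- array(NA_real_, c(30, 30, 2))
  vals[1:30, 1:30, ] <- 0.1             # covered background
  # slice 1: components of 7 and 12 pixels; slice 2: one of 9
  vals[2:8, 2, 1] <- 0.9                # 7 pixels in a row
  vals[15:18, 15:17, 1] <- 0.9          # 12-pixel block
  vals[5:7, 20:22, 2] <- 0.9            # 9-pixel block
  h <- structure(list(values = vals, coverage = array(1L, dim(vals)),
                      pixel_area_mm2 = 1, study_id = "fixture"),
                 class = "heatmap")
  r <- largest_high_risk_area(h, 0.5)
  expect_equal(r$area_mm2, 12)
  expect_equal(r$n_pixels, oracle_largest_region(!is.na(vals) & vals > 0.5))
  expect_equal(r$slice, 0L)

  expect_equal(largest_high_risk_area(h, 0.95)$area_mm2, 0)

  full <- structure(list(values = array(0.7, c(30, 30, 1)),
                         coverage = array(1L, c(30, 30, 1)),
                         pixel_area_mm2 = 1, study_id = "full"),
                    class = "heatmap")
  expect_equal(largest_high_risk_area(full, 0.5)$area_mm2, 900)
})

test_that("area statistic matches the flood-fill oracle and is monotone in t", {
  set.seed(33)
  st <- generate_phantom_study(phantom_spec(), TRUE, 13L)
  ps <- generate_patches(roi_union(st$mask))
  ps$patches$probability <- runif(nrow(ps$patches))
  h <- build_heatmap(ps)
  prev <- Inf
  for (t in c(0.2, 0.4, 0.6, 0.8)) {
    r <- largest_high_risk_area(h, t)
    expect_equal(r$n_pixels,
                 oracle_largest_region(!is.na(h$values) & h$values > t))
    expect_lte(r$area_mm2, prev)
    prev <- r$area_mm2
  }
})

test_that("threshold search scans the 91-point grid and breaks ties low", {
  mk <- function(hot_value, block) {
    vals <- array(NA_real_, c(30, 30, 1))
    vals[1:30, 1:30, 1] <- 0.05          # covered, never above the grid
    vals[block$x, block$y, 1] <- hot_value
    structure(list(values = vals, coverage = array(1L, c(30, 30, 1)),
                   pixel_area_mm2 = 1, study_id = "x"),
              class = "heatmap")
  }
  # cases: 25-pixel blob at 0.9; controls: larger 100-pixel blob whose
  # values top out just above 0.30, so low thresholds rank controls higher
  # and every t in (0.304, 0.9) separates perfectly
  heats <- c(lapply(1:6, function(i)
               mk(0.9, list(x = 3:7, y = 3:7))),
             lapply(1:6, function(i)
               mk(0.304, list(x = 11:20, y = 11:20))))
  labels <- rep(c(1, 0), each = 6)
  res <- search_area_threshold(heats, labels)
  expect_equal(nrow(res$grid), 91)
  expect_equal(res$grid$threshold, 0.05 + 0:90 * 0.01)
  expect_equal(res$auc, 1)
  expect_equal(res$threshold, 0.31)  # first grid point above the controls

  expect_error(search_area_threshold(heats[1:6], rep(1, 6)),
               class = "pancrad_input_error")
})

test_that("threshold search on permuted labels finds no real signal", {
  set.seed(61)
  heats <- lapply(1:40, function(i) {
    vals <- array(NA_real_, c(25, 25, 1))
    vals[1:25, 1:25, 1] <- runif(625, 0, 0.6)
    structure(list(values = vals, coverage = array(1L, c(25, 25, 1)),
                   pixel_area_mm2 = 1, study_id = i),
              class = "heatmap")
  })
  labels <- sample(rep(c(0, 1), each = 20))
  res <- search_area_threshold(heats, labels)
  expect_lt(res$auc, 0.75)
})
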