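test_that("the reference fusion equation evaluates exactly as printed", {
  fm <- paper_fusion_model()
  expect_equal(fm$coef_p3d, 3.95759716)
  expect_equal(fm$coef_area, 0.00241766494)
  expect_equal(fm$intercept, -2.79234888)
  expect_equal(combined_probability(fm, 0, 0),
               1 / (1 + exp(2.79234888)), tolerance = 1e-9)
  expect_equal(combined_probability(fm, 1, 0),
               1 / (1 + exp(-(3.95759716 - 2.79234888))), tolerance = 1e-9)
  expect_equal(combined_probability(fm, 0.5, 1000),
               plogis(-2.79234888 + 3.95759716 * 0.5 +
                        0.00241766494 * 1000), tolerance = 1e-9)
  # strictly increasing in each argument (positive coefficients)
  p_grid <- combined_probability(fm, seq(0, 1, 0.1), 0)
  expect_true(all(diff(p_grid) > 0))
  a_grid <- combined_probability(fm, 0.5, seq(0, 2000, 100))
  expect_true(all(diff(a_grid) > 0))
  expect_error(combined_probability(fm, -0.1, 0),
               class = "pancrad_domain_error")
  expect_error(combined_probability(fm, 0.5, -5),
               class = "pancrad_domain_error")
})

test_that("fusion coefficients are recovered from simulated cohorts", {
  set.seed(501)
  n <- 5000
  truth <- paper_fusion_model()
  p3d <- runif(n)
  area <- rgamma(n, shape = 1.2, scale = 350)
  y <- rbinom(n, 1, combined_probability(truth, p3d, area))
  fit <- fit_fusion(p3d, area, y)
  expect_lt(abs(fit$coef_p3d - truth$coef_p3d) / truth$coef_p3d, 0.15)
  expect_lt(abs(fit$coef_area - truth$coef_area) / truth$coef_area, 0.15)
  expect_false(fit$separation)

  # duplicating the data leaves the ML fit unchanged
  fit2 <- fit_fusion(rep(p3d, 2), rep(area, 2), rep(y, 2))
  expect_equal(fit2$coef_p3d, fit$coef_p3d, tolerance = 1e-6)
  expect_equal(fit2$coef_area, fit$coef_area, tolerance = 1e-6)
})

test_that("null inputs give coefficients whose CIs cover zero", {
  set.seed(502)
  n <- 800
  p3d <- runif(n)
  area <- rgamma(n, 1.2, scale = 300)
  y <- rbinom(n, 1, 0.4)          # label independent of both inputs
  fit <- fit_fusion(p3d, area, y)
  z1 <- abs(fit$coef_p3d / fit$se[2])
  z2 <- abs(fit$coef_area / fit$se[3])
  expect_lt(z1, 1.96)
  expect_lt(z2, 1.96)
})

test_that("perfect separation falls back to a penalized fit", {
  p3d <- c(runif(30, 0, 0.3), runif(30, 0.7, 1))
  area <- rep(0, 60)
  y <- rep(c(0, 1), each = 30)
  fit <- fit_fusion(p3d, area, y)
  expect_true(fit$separation)
  expect_true(all(is.finite(c(fit$intercept, fit$coef_p3d,
                              fit$coef_area))))
})

test_that("Youden cutoffs maximize J over score midpoints", {
  scores <- c(0.1, 0.4, 0.35, 0.8)
  labels <- c(0, 0, 1, 1)
  yc <- youden_cutoff(scores, labels)
  # brute force over all midpoints and the infinities
  s <- sort(unique(scores))
  cand <- c(-Inf, (s[-1] + s[-length(s)]) / 2, Inf)
  j <- vapply(cand, function(ct)
    mean(scores[labels == 1] > ct) + mean(scores[labels == 0] <= ct) - 1, 0)
  expect_equal(yc$youden, max(j))
  expect_equal(yc$cutoff, cand[which.max(j)])

  sep <- youden_cutoff(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(sep$youden, 1)
  expect_gt(sep$cutoff, 3)
  expect_lt(sep$cutoff, 10)

  flat <- youden_cutoff(rep(0.5, 10), rep(c(0, 1), 5))
  expect_equal(flat$youden, 0)
})

test_that("decision rules implement the full series/parallel truth table", {
  cutoffs <- list(p3d = 0.5, area2d = 100, p_combined = 0.5)
  grid <- expand.grid(hi3d = c(FALSE, TRUE), hi2d = c(FALSE, TRUE))
  d <- decide(p3d = ifelse(grid$hi3d, 0.9, 0.1),
              area2d = ifelse(grid$hi2d, 500, 0),
              p_combined = rep(0.9, 4), cutoffs)
  expect_equal(d$call3d, grid$hi3d)
  expect_equal(d$call2d, grid$hi2d)
  expect_equal(d$call_series, grid$hi3d & grid$hi2d)
  expect_equal(d$call_parallel, grid$hi3d | grid$hi2d)
  # scores exactly at the cutoff are negative (strict >)
  eq <- decide(0.5, 100, 0.5, cutoffs)
  expect_false(eq$call3d)
  expect_false(eq$call2d)
  expect_false(eq$call_combined)
  expect_error(decide(NA, 1, 0.5, cutoffs),
               class = "pancrad_incomplete_study_error")
})

test_that("series and parallel calls bracket the individual analyses", {
  set.seed(503)
  for (rep in 1:5) {
    n <- 120
    y <- rbinom(n, 1, 0.45)
    p3d <- plogis(rnorm(n, y * 1.5))
    area <- rgamma(n, 1 + 2 * y, scale = 150)
    pc <- combined_probability(paper_fusion_model(), p3d, area)
    cutoffs <- list(p3d = 0.5, area2d = 200, p_combined = 0.4)
    d <- decide(p3d, area, pc, cutoffs)
    expect_true(all(d$call_series <= d$call_parallel))
    sens <- function(calls) mean(calls[y == 1])
    spec <- function(calls) mean(!calls[y == 0])
    expect_lte(sens(d$call_series), min(sens(d$call3d), sens(d$call2d)))
    expect_gte(spec(d$call_series), max(spec(d$call3d), spec(d$call2d)))
    expect_gte(sens(d$call_parallel), max(sens(d$call3d), sens(d$call2d)))
    expect_lte(spec(d$call_parallel), min(spec(d$call3d), spec(d$call2d)))
  }
})
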