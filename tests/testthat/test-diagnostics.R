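test_that("Clopper-Pearson intervals match published worked values", {
  ci <- proportion_ci(65, 92)
  expect_equal(ci$point, 65 / 92, tolerance = 1e-6)
  expect_equal(ci$lower, 0.602, tolerance = 1e-3)
  expect_equal(ci$upper, 0.797, tolerance = 1e-3)
  ci2 <- proportion_ci(196, 199)
  expect_equal(ci2$lower, 0.957, tolerance = 1e-3)
  expect_equal(ci2$upper, 0.997, tolerance = 1e-3)
  expect_equal(proportion_ci(0, 25)$lower, 0)
  expect_equal(proportion_ci(25, 25)$upper, 1)
  expect_error(proportion_ci(1, 0), class = "pancrad_domain_error")
  # agrees with the exact binomial test inversion
  bt <- binom.test(37, 120)$conf.int
  ci3 <- proportion_ci(37, 120)
  expect_equal(c(ci3$lower, ci3$upper), as.numeric(bt), tolerance = 1e-9)
})

test_that("accuracy metrics recompute the published series row", {
  cc <- confusion_counts(calls = c(rep(1, 498), rep(0, 173), rep(1, 39),
                                   rep(0, 766)),
                         truth = c(rep(1, 671), rep(0, 805)))
  m <- accuracy_metrics(cc)
  expect_equal(m$point[m$metric == "sensitivity"], 0.742, tolerance = 5e-4)
  expect_equal(m$point[m$metric == "specificity"], 0.952, tolerance = 5e-4)
  expect_equal(m$point[m$metric == "accuracy"], 0.856, tolerance = 5e-4)
  # acc = sens * prevalence + spec * (1 - prevalence)
  prev <- 671 / 1476
  expect_equal(m$point[3], m$point[1] * prev + m$point[2] * (1 - prev),
               tolerance = 1e-12)
  perfect <- accuracy_metrics(confusion_counts(c(1, 1, 0, 0),
                                               c(1, 1, 0, 0)))
  expect_true(all(perfect$point == 1))
})

test_that("likelihood ratios use the log-method CI", {
  cc <- list(tp = 498, fn = 173, fp = 39, tn = 766)
  lr <- likelihood_ratios(structure(cc, class = "confusion_counts"))
  expect_lt(abs(lr$point[1] - 15.32), 0.01)
  expect_lt(abs(lr$lower[1] - 11.24), 0.02)
  expect_lt(abs(lr$upper[1] - 20.87), 0.02)
  expect_lt(abs(lr$point[2] - 0.27), 0.01)
  # an uninformative test has LR+ = 1
  unin <- likelihood_ratios(confusion_counts(rep(c(1, 0), 50),
                                             rep(c(1, 1, 0, 0), 25)))
  expect_equal(unin$point[1], 1, tolerance = 1e-9)
})

test_that("cross-tab cell LRs reproduce both published cohorts", {
  nat <- cross_tab(pc = c(498, 36, 80, 57), control = c(39, 25, 104, 637))
  lr <- stratum_likelihood_ratios(nat)
  expect_lt(max(abs(lr$point - c(15.32, 1.73, 0.92, 0.11))), 0.01)
  expect_lt(max(abs(lr$lower - c(11.24, 1.05, 0.70, 0.08))), 0.02)
  expect_lt(max(abs(lr$upper - c(20.87, 2.85, 1.21, 0.14))), 0.02)

  loc <- cross_tab(pc = c(80, 4, 12, 13), control = c(3, 4, 12, 128))
  lrl <- stratum_likelihood_ratios(loc)
  expect_lt(abs(lrl$point[1] - 35.96), 0.01)
  expect_lt(abs(lrl$point[4] - 0.14), 0.005)
  expect_lt(abs(lrl$lower[1] - 11.67), 0.02)
  expect_lt(abs(lrl$upper[1] - 110.85), 0.02)

  unif <- cross_tab(pc = c(10, 10, 10, 10), control = c(20, 20, 20, 20))
  expect_true(all(abs(stratum_likelihood_ratios(unif)$point - 1) < 1e-12))
})

test_that("AUC equals the pairwise oracle and matches pROC", {
  skip_if_not_installed("pROC")
  set.seed(71)
  for (rep in 1:5) {
    n <- 40
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(n, y), 1)   # rounding forces ties
    a <- roc_auc(s, y)
    expect_equal(a$point, oracle_auc(s, y), tolerance = 1e-12)
    r <- pROC::roc(y, s, quiet = TRUE, direction = "<")
    expect_equal(a$point, as.numeric(pROC::auc(r)), tolerance = 1e-12)
    ci <- suppressMessages(pROC::ci.auc(r, method = "delong"))
    expect_equal(a$lower, max(0, as.numeric(ci)[1]), tolerance = 1e-9)
    expect_equal(a$upper, min(1, as.numeric(ci)[3]), tolerance = 1e-9)
  }
  sep <- roc_auc(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))
  expect_equal(sep$point, 1)
})

test_that("random scores give chance-level AUC", {
  set.seed(72)
  s <- rnorm(400)
  y <- rep(c(0, 1), each = 200)
  a <- roc_auc(s, y)
  expect_gt(a$point, 0.42)
  expect_lt(a$point, 0.58)
})

test_that("the paired DeLong test matches pROC and detects planted signal", {
  skip_if_not_installed("pROC")
  set.seed(73)
  n <- 300
  y <- rep(c(0, 1), each = n / 2)
  informative <- y + rnorm(n, sd = 0.8)
  noise <- rnorm(n)
  dl <- delong_paired_test(informative, noise, y)
  expect_lt(dl$p_value, 0.01)
  pr <- suppressMessages(pROC::roc.test(
    pROC::roc(y, informative, quiet = TRUE, direction = "<"),
    pROC::roc(y, noise, quiet = TRUE, direction = "<"),
    method = "delong", paired = TRUE))
  expect_equal(dl$p_value, pr$p.value, tolerance = 1e-8)

  same <- delong_paired_test(informative, informative, y)
  expect_equal(same$delta, 0)
  expect_equal(same$p_value, 1)
})

test_that("size-stratified sensitivity reproduces the published strata", {
  calls <- c(rep(1, 65), rep(0, 27),     # <2cm: 65/92
             rep(1, 355), rep(0, 25),    # 2-4cm: 355/380
             rep(1, 196), rep(0, 3))     # >4cm: 196/199
  stratum <- c(rep("<2cm", 92), rep("2-4cm", 380), rep(">4cm", 199))
  r <- size_stratified_sensitivity(calls, stratum)
  expect_equal(r$table$point, c(0.707, 0.934, 0.985), tolerance = 5e-4)
  expect_equal(r$table$lower, c(0.602, 0.904, 0.957), tolerance = 1e-3)
  expect_equal(r$table$upper, c(0.797, 0.957, 0.997), tolerance = 1e-3)
  expect_lt(r$p_trend, 0.001)

  all_hit <- size_stratified_sensitivity(rep(1, 30),
                                         rep(c("<2cm", "2-4cm", ">4cm"),
                                             each = 10))
  expect_true(all(all_hit$table$point == 1))
})

test_that("the trend test is calibrated under the null", {
  set.seed(74)
  reps <- 500
  p <- vapply(seq_len(reps), function(i) {
    det <- rbinom(3, c(40, 40, 40), 0.6)   # equal sensitivity everywhere
    r <- size_stratified_sensitivity(
      c(rep(1, det[1]), rep(0, 40 - det[1]),
        rep(1, det[2]), rep(0, 40 - det[2]),
        rep(1, det[3]), rep(0, 40 - det[3])),
      rep(c("<2cm", "2-4cm", ">4cm"), each = 40))
    r$p_trend
  }, 0)
  # rejection rate stays near the nominal level (the chi-square reference
  # is approximate and the counts are discrete, so a band is appropriate)
  expect_gt(mean(p < 0.05, na.rm = TRUE), 0.01)
  expect_lt(mean(p < 0.05, na.rm = TRUE), 0.10)
  expect_gt(mean(p < 0.5, na.rm = TRUE), 0.35)
  expect_lt(mean(p < 0.5, na.rm = TRUE), 0.65)
})

test_that("the feature screen separates real effects from noise", {
  set.seed(75)
  n <- 50
  g <- rep(c(0, 1), each = n / 2)
  null_feats <- matrix(rnorm(n * 1000), n, 1000,
                       dimnames = list(NULL, paste0("f", 1:1000)))
  scr <- feature_screen(null_feats, g)
  expect_lte(scr$n_below, 6)   # ~0.1% expected at p < 0.001

  disjoint <- c(rnorm(n / 2, 0, 0.1), rnorm(n / 2, 10, 0.1))
  scr2 <- feature_screen(cbind(sep = disjoint), g)
  expect_lt(scr2$p_values[["sep"]], 1e-10)

  binary <- cbind(flag = c(rep(0, 20), rep(1, 5), rep(0, 5), rep(1, 20)))
  scr3 <- feature_screen(binary, g)
  expect_equal(scr3$p_values[["flag"]],
               fisher.test(table(binary[, 1], g))$p.value)
})

test_that("the U statistic equals the pairwise count on small samples", {
  set.seed(76)
  for (rep in 1:5) {
    x <- round(rnorm(15), 1)
    y <- round(rnorm(12), 1)
    u <- 0
    for (a in x) for (b in y) u <- u + (a > b) + 0.5 * (a == b)
    expect_equal(mann_whitney_u(x, y), u)
  }
})

test_that("exact McNemar compares paired calls via discordant pairs", {
  a <- c(rep(1, 60), rep(0, 40))
  b <- c(rep(1, 40), rep(0, 20), rep(1, 5), rep(0, 35))
  r <- mcnemar_exact(a, b)
  expect_equal(r$b, sum(a == 1 & b == 0))
  expect_equal(r$c, sum(a == 0 & b == 1))
  expect_equal(r$p_value, binom.test(r$b, r$b + r$c, 0.5)$p.value)
  expect_equal(mcnemar_exact(a, a)$p_value, 1)
})
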