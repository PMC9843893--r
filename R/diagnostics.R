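# Cohort-level diagnostic accuracy: exact binomial (Clopper-Pearson)
# confidence intervals for proportions, likelihood ratios with log-method
# CIs, rank-based AUC with DeLong variance and the paired DeLong test,
# size-stratified sensitivity with a Cochran-Armitage trend test, paired
# sensitivity comparison by exact McNemar, and a univariate feature screen.
# All intervals are two-sided 95% with no multiplicity correction.

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' @param successes number of successes (vectorized).
#' @param n number of trials (>= 1).
#' @param conf_level confidence level (default 0.95).
#' @return data.frame: `point`, `lower`, `upper`, `method`.
#' @export
proportion_ci <- function(successes, n, conf_level = 0.95) {
  if (any(n < 1)) stop_pancrad("n must be >= 1", "pancrad_domain_error")
  if (any(successes < 0 | successes > n))
    stop_pancrad("successes must lie in [0, n]", "pancrad_domain_error")
  a <- (1 - conf_level) / 2
  lower <- ifelse(successes == 0, 0, qbeta(a, successes, n - successes + 1))
  upper <- ifelse(successes == n, 1,
                  qbeta(1 - a, successes + 1, n - successes))
  data.frame(point = successes / n, lower = lower, upper = upper,
             method = "exact-binomial")
}

#' Confusion counts from calls and truth
#'
#' @param calls logical/binary predicted positives.
#' @param truth logical/binary true labels (1 = cancer).
#' @return A `confusion_counts` list: `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(calls, truth) {
  calls <- as_label01(calls)
  truth <- as_label01(truth)
  stopifnot(length(calls) == length(truth))
  structure(list(tp = sum(calls == 1 & truth == 1),
                 fp = sum(calls == 1 & truth == 0),
                 tn = sum(calls == 0 & truth == 0),
                 fn = sum(calls == 0 & truth == 1)),
            class = "confusion_counts")
}

#' Sensitivity, specificity and accuracy with exact CIs
#'
#' @param counts a [confusion_counts()] list.
#' @return data.frame, one row per metric, with the exact binomial CI.
#' @export
accuracy_metrics <- function(counts) {
  with(counts, {
    if (tp + fn == 0 || tn + fp == 0)
      stop_pancrad("a class is empty; metrics undefined",
                   "pancrad_input_error")
    out <- rbind(
      cbind(metric = "sensitivity", proportion_ci(tp, tp + fn)),
      cbind(metric = "specificity", proportion_ci(tn, tn + fp)),
      cbind(metric = "accuracy", proportion_ci(tp + tn, tp + fp + tn + fn)))
    out
  })
}

# Likelihood ratio (a/n1) / (b/n0) with the Simel log-method CI:
# ln LR +/- z * sqrt(1/a - 1/n1 + 1/b - 1/n0).
lr_log_method <- function(a, n1, b, n0, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  point <- (a / n1) / (b / n0)
  if (a == 0 || b == 0) {
    # zero cell: point may be 0 or Inf; one usable bound only
    return(data.frame(point = point, lower = if (a == 0) 0 else NA_real_,
                      upper = if (b == 0) Inf else NA_real_,
                      method = "log-LR"))
  }
  se <- sqrt(1 / a - 1 / n1 + 1 / b - 1 / n0)
  data.frame(point = point,
             lower = exp(log(point) - z * se),
             upper = exp(log(point) + z * se),
             method = "log-LR")
}

#' Positive and negative likelihood ratios with log-method CIs
#'
#' LR+ = sensitivity / (1 - specificity); LR- = (1 - sensitivity) /
#' specificity. CIs use the log method on the two defining proportions.
#'
#' @param counts a [confusion_counts()] list.
#' @return data.frame with rows `lr_positive`, `lr_negative`.
#' @export
likelihood_ratios <- function(counts) {
  with(counts, {
    n1 <- tp + fn
    n0 <- tn + fp
    rbind(cbind(metric = "lr_positive", lr_log_method(tp, n1, fp, n0)),
          cbind(metric = "lr_negative", lr_log_method(fn, n1, tn, n0)))
  })
}

#' Cross-tabulated counts over the four (3D call, 2D call) cells
#'
#' @param pc,control integer length-4 counts in cell order
#'   `3d+2d+`, `3d+2d-`, `3d-2d+`, `3d-2d-`.
#' @return A `cross_tab` object.
#' @export
cross_tab <- function(pc, control) {
  stopifnot(length(pc) == 4, length(control) == 4,
            all(pc >= 0), all(control >= 0))
  cells <- c("3d+2d+", "3d+2d-", "3d-2d+", "3d-2d-")
  structure(list(cells = cells, pc = as.integer(pc),
                 control = as.integer(control)),
            class = "cross_tab")
}

#' Per-cell likelihood ratios of a cross-tab
#'
#' Each cell's LR is the fraction of cancer studies falling in the cell over
#' the fraction of controls, with a log-method CI on the cell counts.
#'
#' @param tab a [cross_tab()].
#' @return data.frame with one row per cell.
#' @export
stratum_likelihood_ratios <- function(tab) {
  stopifnot(inherits(tab, "cross_tab"))
  n1 <- sum(tab$pc)
  n0 <- sum(tab$control)
  if (n1 == 0 || n0 == 0)
    stop_pancrad("cross-tab row sums must be positive",
                 "pancrad_input_error")
  out <- do.call(rbind, lapply(seq_len(4), function(i)
    lr_log_method(tab$pc[i], n1, tab$control[i], n0)))
  cbind(cell = tab$cells, out)
}

# ---- AUC / DeLong -----------------------------------------------------

# Rank-based Mann-Whitney AUC; ties count one half.
auc_mw <- function(scores, labels) {
  y <- as_label01(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop_pancrad("both classes are required for AUC", "pancrad_input_error")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong structural components: V10 (per case), V01 (per control).
delong_components <- function(scores, y) {
  cases <- scores[y == 1]
  controls <- scores[y == 0]
  v10 <- vapply(cases, function(s)
    mean((s > controls) + 0.5 * (s == controls)), 0)
  v01 <- vapply(controls, function(s)
    mean((cases > s) + 0.5 * (cases == s)), 0)
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' AUC with DeLong confidence interval
#'
#' Mann-Whitney AUC (ties count one half) with the DeLong variance
#' estimator for the 95% CI, truncated to \[0, 1\].
#'
#' @param scores numeric scores.
#' @param labels binary labels (1 = cancer).
#' @param conf_level confidence level (default 0.95).
#' @return data.frame: `point`, `lower`, `upper`, `method`.
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  y <- as_label01(labels)
  cmp <- delong_components(scores, y)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  v <- var(cmp$v10) / n1 + var(cmp$v01) / n0
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(point = cmp$auc,
             lower = max(0, cmp$auc - z * sqrt(v)),
             upper = min(1, cmp$auc + z * sqrt(v)),
             method = "DeLong")
}

#' Paired DeLong test for two correlated AUCs
#'
#' Both score vectors must cover the same studies in the same order. The
#' two-sided p-value uses the paired DeLong variance of the AUC difference.
#'
#' @param scores_a,scores_b score vectors from the two analyses.
#' @param labels binary labels (1 = cancer).
#' @return list: `auc_a`, `auc_b`, `delta`, `z`, `p_value`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  y <- as_label01(labels)
  stopifnot(length(scores_a) == length(y), length(scores_b) == length(y))
  ca <- delong_components(scores_a, y)
  cb <- delong_components(scores_b, y)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  delta <- ca$auc - cb$auc
  if (var_delta <= 0) {
    z <- if (delta == 0) 0 else sign(delta) * Inf
  } else {
    z <- delta / sqrt(var_delta)
  }
  list(auc_a = ca$auc, auc_b = cb$auc, delta = delta, z = z,
       p_value = 2 * pnorm(-abs(z)))
}

# ---- stratified sensitivity and paired comparison ---------------------

#' Sensitivity stratified by tumor size with a trend test
#'
#' Strata follow the clinical cuts < 2 cm, 2-4 cm, > 4 cm. Each stratum's
#' sensitivity gets an exact binomial CI; the monotone trend over ordered
#' strata is tested with the Cochran-Armitage test using equally spaced
#' stratum scores.
#'
#' @param calls binary predicted positives for cancer studies.
#' @param stratum factor/character stratum per cancer study; ordered
#'   `"<2cm"`, `"2-4cm"`, `">4cm"` (unused levels are dropped).
#' @return list: `table` (per-stratum detected/total with CI) and
#'   `p_trend`.
#' @export
size_stratified_sensitivity <- function(calls, stratum) {
  calls <- as_label01(calls)
  lv <- c("<2cm", "2-4cm", ">4cm")
  stratum <- factor(as.character(stratum), levels = lv)
  if (anyNA(stratum))
    stop_pancrad("stratum labels must be <2cm, 2-4cm or >4cm",
                 "pancrad_input_error")
  keep <- lv[lv %in% levels(droplevels(stratum))]
  det <- tapply(calls, stratum, sum)[keep]
  tot <- table(stratum)[keep]
  ci <- proportion_ci(as.integer(det), as.integer(tot))
  tab <- cbind(stratum = keep, detected = as.integer(det),
               total = as.integer(tot), ci)
  pooled <- sum(det) / sum(tot)
  p_trend <- if (length(keep) > 1 && pooled > 0 && pooled < 1)
    unname(suppressWarnings(
      prop.trend.test(as.integer(det), as.integer(tot),
                      score = seq_along(keep)))$p.value)
  else NA_real_   # a flat 0%/100% detection rate carries no trend signal
  list(table = tab, p_trend = p_trend)
}

#' Exact McNemar comparison of two analyses' paired calls
#'
#' Compares detection by two analyses on the same studies using the exact
#' binomial test on discordant pairs. The test on Ptrend and this pairwise
#' method are stated choices of this package (users should treat the named
#' tests, not any other convention, as the ones applied).
#'
#' @param calls_a,calls_b binary calls on the same studies.
#' @return list: `b` (a+ b-), `c` (a- b+), `p_value`.
#' @export
mcnemar_exact <- function(calls_a, calls_b) {
  a <- as_label01(calls_a)
  b <- as_label01(calls_b)
  stopifnot(length(a) == length(b))
  n10 <- sum(a == 1 & b == 0)
  n01 <- sum(a == 0 & b == 1)
  p <- if (n10 + n01 == 0) 1 else
    binom.test(n10, n10 + n01, 0.5)$p.value
  list(b = n10, c = n01, p_value = p)
}

#' Univariate feature screen between two groups
#'
#' Continuous features are compared with the Mann-Whitney U test; features
#' with at most two distinct values are treated as binary and compared with
#' Fisher's exact test. Reports the count of features with p below the
#' threshold.
#'
#' @param features numeric matrix (rows = studies, columns = features).
#' @param groups binary group labels.
#' @param threshold significance threshold for the summary count
#'   (default 0.001).
#' @return list: `p_values` (named), `n_below`, `fraction_below`,
#'   `threshold`.
#' @export
feature_screen <- function(features, groups, threshold = 0.001) {
  y <- as_label01(groups)
  if (length(unique(y)) < 2)
    stop_pancrad("two groups are required", "pancrad_input_error")
  features <- as.matrix(features)
  p <- apply(features, 2, function(v) {
    if (length(unique(v)) <= 2) {
      if (length(unique(v)) < 2) return(1)
      fisher.test(table(factor(v), factor(y)))$p.value
    } else {
      # default exact/normal switch of wilcox.test; tie warnings are
      # expected with discretized features
      suppressWarnings(wilcox.test(v[y == 1], v[y == 0])$p.value)
    }
  })
  list(p_values = p, n_below = sum(p < threshold),
       fraction_below = mean(p < threshold), threshold = threshold)
}

# Brute-force Mann-Whitney U statistic used nowhere in the screen itself;
# exported for transparency of the AUC/U relationship.
#' @rdname feature_screen
#' @param x,y numeric samples; `mann_whitney_u` returns the U statistic of
#'   `x` over `y` with ties counting one half.
#' @export
mann_whitney_u <- function(x, y) {
  r <- rank(c(x, y), ties.method = "average")
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}
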