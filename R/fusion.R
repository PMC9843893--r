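# Fusion of the two branches: the 3D branch probability and the 2D branch
# high-risk area (mm^2) enter a logistic regression fitted on validation
# studies; operating cutoffs for each score are chosen by the maximum
# Youden index; series/parallel combination rules give the
# high-specificity / high-sensitivity operating modes.

#' The published fusion model coefficients
#'
#' The reference logistic fusion model shipped as a versioned constant:
#' `logit(p) = 3.95759716 * p3d + 0.00241766494 * area2d - 2.79234888`,
#' with `p3d` the 3D branch probability and `area2d` the high-risk area in
#' mm^2.
#'
#' @return A `fusion_model` with elements `intercept`, `coef_p3d`,
#'   `coef_area`.
#' @export
paper_fusion_model <- function() {
  structure(list(intercept = -2.79234888,
                 coef_p3d = 3.95759716,
                 coef_area = 0.00241766494,
                 source = "reference-fixture"),
            class = "fusion_model")
}

#' @exportS3Method base::print
print.fusion_model <- function(x, ...) {
  cat(sprintf("<fusion_model> logit(p) = %.8f * p3d + %.11f * area2d + %.8f  [%s]\n",
              x$coef_p3d, x$coef_area, x$intercept, x$source))
  invisible(x)
}

#' Fit the logistic fusion model on validation outputs
#'
#' Maximum-likelihood logistic regression of the study label on the 3D
#' probability and the 2D area. Perfect separation is detected (unbounded
#' coefficients) and handled by refitting with a light ridge penalty; the
#' result is flagged via `separation = TRUE`.
#'
#' @param p3d numeric vector of 3D branch probabilities in \[0, 1\].
#' @param area2d numeric vector of high-risk areas (mm^2, >= 0).
#' @param labels binary study labels (1 = cancer).
#' @return A `fusion_model` with full-precision coefficients, standard
#'   errors (ML fit only) and the fit source.
#' @export
fit_fusion <- function(p3d, area2d, labels) {
  y <- as_label01(labels)
  if (length(unique(y)) < 2)
    stop_pancrad("both classes are required to fit the fusion model",
                 "pancrad_input_error")
  stopifnot(length(p3d) == length(y), length(area2d) == length(y))
  df <- data.frame(y = y, p3d = p3d, area2d = area2d)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ p3d + area2d, family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA, 3))
  if (sep || any(!is.finite(cf)) || max(abs(cf)) > 1e3) {
    # separation: ridge-penalized fall-back keeps coefficients finite
    sep <- TRUE
    x <- as.matrix(df[, c("p3d", "area2d")])
    gfit <- suppressWarnings(
      glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                     lambda = 1e-3, standardize = FALSE))
    cf <- c(as.numeric(gfit$a0), as.numeric(gfit$beta))
    se <- rep(NA_real_, 3)
  }
  structure(list(intercept = unname(cf[1]), coef_p3d = unname(cf[2]),
                 coef_area = unname(cf[3]),
                 se = unname(se), separation = sep, n = length(y),
                 source = if (sep) "ridge-fallback" else "ml-fit"),
            class = "fusion_model")
}

#' Combined probability of cancer for a study
#'
#' @param model a `fusion_model`.
#' @param p3d 3D branch probability in \[0, 1\].
#' @param area2d 2D branch high-risk area in mm^2 (>= 0).
#' @return `1 / (1 + exp(-(b0 + b1 * p3d + b2 * area2d)))`, vectorized.
#' @export
combined_probability <- function(model, p3d, area2d) {
  stopifnot(inherits(model, "fusion_model"))
  if (any(p3d < 0 | p3d > 1))
    stop_pancrad("p3d must be within [0, 1]", "pancrad_domain_error")
  if (any(area2d < 0))
    stop_pancrad("area2d must be non-negative", "pancrad_domain_error")
  plogis(model$intercept + model$coef_p3d * p3d + model$coef_area * area2d)
}

#' Operating cutoff by the maximum Youden index
#'
#' Candidate cutoffs are the midpoints between adjacent distinct sorted
#' scores plus -Inf and +Inf; a study is called positive when its score is
#' strictly above the cutoff. The cutoff maximizing J = sensitivity +
#' specificity - 1 is returned, ties broken toward the lower cutoff.
#'
#' @param scores numeric score vector.
#' @param labels binary labels (1 = cancer).
#' @return A list: `cutoff`, `youden`, `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(scores, labels) {
  y <- as_label01(labels)
  if (length(unique(y)) < 2)
    stop_pancrad("both classes are required for cutoff selection",
                 "pancrad_input_error")
  s <- sort(unique(scores))
  cand <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  j <- vapply(cand, function(ct)
    sum(scores > ct & y == 1) / n1 + sum(scores <= ct & y == 0) / n0 - 1, 0)
  best <- which.max(j)  # first (lowest cutoff) on ties
  list(cutoff = cand[best], youden = j[best],
       sensitivity = sum(scores > cand[best] & y == 1) / n1,
       specificity = sum(scores <= cand[best] & y == 0) / n0)
}

#' Study-level decisions from branch scores and cutoffs
#'
#' Applies the per-branch cutoffs (strict `>` for a positive call) and the
#' combination rules: series positive iff both branches positive, parallel
#' positive iff either is.
#'
#' @param p3d,area2d,p_combined numeric score vectors (equal length).
#' @param cutoffs list with numeric elements `p3d`, `area2d`, `p_combined`.
#' @param study_id optional ids.
#' @return data.frame with logical columns `call3d`, `call2d`,
#'   `call_combined`, `call_series`, `call_parallel` (TRUE = positive).
#' @export
decide <- function(p3d, area2d, p_combined, cutoffs, study_id = NULL) {
  if (anyNA(p3d) || anyNA(area2d) || anyNA(p_combined))
    stop_pancrad("all three scores are required for every study",
                 "pancrad_incomplete_study_error")
  stopifnot(all(c("p3d", "area2d", "p_combined") %in% names(cutoffs)))
  call3d <- p3d > cutoffs$p3d
  call2d <- area2d > cutoffs$area2d
  callc <- p_combined > cutoffs$p_combined
  data.frame(study_id = study_id %||% seq_along(p3d),
             p3d = p3d, area2d = area2d, p_combined = p_combined,
             call3d = call3d, call2d = call2d, call_combined = callc,
             call_series = call3d & call2d,
             call_parallel = call3d | call2d)
}
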