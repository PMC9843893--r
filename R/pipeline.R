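# End-to-end orchestration: extract -> train -> predict -> evaluate.
# The pipeline consumes a cohort (in memory or a directory of NIfTI pairs
# plus a manifest CSV), produces per-study 3D feature rows and per-patch 2D
# feature rows, trains both branch models with validation-AUC early
# stopping, searches the heatmap pixel threshold on the validation split,
# fits (or fixes) the logistic fusion, selects Youden cutoffs, and reports
# cohort-level diagnostic accuracy.

#' Pipeline configuration
#'
#' @param resample a [resample_spec()].
#' @param manifest3d,manifest2d feature manifests for the two branches.
#' @param bin_width texture bin width in HU.
#' @param patch_size,stride,min_overlap_frac patch lattice parameters.
#' @param training a [training_config()].
#' @param connectivity high-risk region connectivity (`"2d8"`, `"2d4"`,
#'   `"3d26"`).
#' @param fusion_source `"fit"` (logistic fit on validation) or `"paper"`
#'   (the shipped reference coefficients).
#' @param seed root seed; all pipeline randomness derives from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(resample = resample_spec(),
                            manifest3d = default_manifest_3d(),
                            manifest2d = default_manifest_2d(),
                            bin_width = 16, patch_size = 20L, stride = 5L,
                            min_overlap_frac = 0.05,
                            training = training_config(),
                            connectivity = "2d8",
                            fusion_source = c("fit", "paper"),
                            seed = 1L) {
  structure(list(resample = resample, manifest3d = manifest3d,
                 manifest2d = manifest2d, bin_width = bin_width,
                 patch_size = as.integer(patch_size),
                 stride = as.integer(stride),
                 min_overlap_frac = min_overlap_frac, training = training,
                 connectivity = connectivity,
                 fusion_source = match.arg(fusion_source),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Load a cohort written by generate_cohort(dir = ...)
read_cohort_dir <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"),
                  stringsAsFactors = FALSE)
  studies <- lapply(seq_len(nrow(man)), function(k) {
    id <- man$study_id[k]
    list(volume = read_volume(file.path(dir, paste0(id, "_ct.nii.gz"))),
         mask = read_mask(file.path(dir, paste0(id, "_mask.nii.gz"))),
         case = man$label[k] == 1,
         tumor_diameter_mm = man$tumor_diameter_mm[k],
         stratum = man$stratum[k])
  })
  structure(list(studies = studies, manifest = man, spec = NULL),
            class = "phantom_cohort")
}

#' Extract 3D and 2D feature tables for a cohort
#'
#' Resamples every volume/mask pair onto the canonical grid, computes the
#' whole-pancreas 3D feature vector and the per-patch 2D feature matrix
#' with training labels. Studies whose post-resampling ROI is empty are
#' excluded with a logged record and the run continues.
#'
#' @param cohort a `phantom_cohort` (or the value of [read_cohort_dir] for
#'   on-disk cohorts).
#' @param config a [pipeline_config()].
#' @param output_dir optional; writes `features3d.csv`, `patches.csv` and
#'   `exclusions.jsonl` audit files.
#' @return An `extraction` object: `study_id`, `truth`, `stratum`, `x3d`
#'   (matrix), `patch` (per-study list of `patchset` and feature matrix
#'   `x`), `exclusions`.
#' @export
run_extract <- function(cohort, config = pipeline_config(),
                        output_dir = NULL) {
  man <- cohort$manifest
  n <- nrow(man)
  x3d <- NULL
  patch <- vector("list", n)
  keep <- logical(n)
  exclusions <- list()
  for (k in seq_len(n)) {
    st <- cohort$studies[[k]]
    rs <- resample_pair(st$volume, st$mask, config$resample)
    roi <- roi_union(rs$mask)
    if (isTRUE(attr(roi, "empty"))) {
      exclusions[[length(exclusions) + 1]] <-
        list(study_id = man$study_id[k], reason = "empty-segmentation")
      next
    }
    keep[k] <- TRUE
    fv <- extract_feature_vector(rs$volume, roi, mode = "3d",
                                 manifest = config$manifest3d,
                                 bin_width = config$bin_width)
    x3d <- rbind(x3d, fv)
    ps <- generate_patches(roi, config$patch_size, config$stride,
                           config$min_overlap_frac,
                           study_id = man$study_id[k])
    ps <- label_patches(ps, rs$mask)
    xp <- study_patch_features(rs$volume, rs$mask, ps,
                               manifest = config$manifest2d,
                               bin_width = config$bin_width)
    patch[[k]] <- list(patchset = ps, x = xp)
  }
  if (is.null(x3d))
    x3d <- matrix(numeric(0), nrow = 0, ncol = nrow(config$manifest3d),
                  dimnames = list(NULL, config$manifest3d$name))
  rownames(x3d) <- man$study_id[keep]
  out <- structure(list(study_id = man$study_id[keep],
                        truth = man$label[keep],
                        stratum = man$stratum[keep],
                        x3d = x3d, patch = patch[keep],
                        exclusions = exclusions,
                        config = config),
                   class = "extraction")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(data.frame(study_id = out$study_id, truth = out$truth,
                         out$x3d, check.names = FALSE),
              file.path(output_dir, "features3d.csv"), row.names = FALSE)
    pt <- do.call(rbind, lapply(out$patch, function(p)
      patch_table(p$patchset)))
    write.csv(pt, file.path(output_dir, "patches.csv"), row.names = FALSE)
    writeLines(vapply(exclusions, function(e)
      jsonlite::toJSON(e, auto_unbox = TRUE), ""),
      file.path(output_dir, "exclusions.jsonl"))
  }
  out
}

#' Train the full model bundle
#'
#' Trains the 2D patch classifier (training-split patches vs
#' validation-split patches), scores validation patches into heatmaps and
#' searches the high-risk pixel threshold, trains the 3D study classifier,
#' fits the logistic fusion on validation outputs (or fixes the reference
#' coefficients), and selects Youden cutoffs for all three scores on the
#' validation split.
#'
#' @param extraction an `extraction` from [run_extract()].
#' @param roles character per retained study: `"train"` or `"valid"`.
#' @param config a [pipeline_config()].
#' @return A `model_bundle`.
#' @export
run_train <- function(extraction, roles, config = pipeline_config()) {
  stopifnot(length(roles) == length(extraction$study_id),
            all(roles %in% c("train", "valid")))
  tr <- roles == "train"
  va <- roles == "valid"
  if (!any(tr) || !any(va) ||
      length(unique(extraction$truth[tr])) < 2 ||
      length(unique(extraction$truth[va])) < 2)
    stop_pancrad("degenerate train/validation split",
                 "pancrad_training_error")
  patch_xy <- function(sel) {
    x <- do.call(rbind, lapply(extraction$patch[sel], `[[`, "x"))
    y <- unlist(lapply(extraction$patch[sel], function(p)
      as.integer(p$patchset$patches$label == "cancerous")))
    list(x = x, y = y)
  }
  ptr <- patch_xy(tr)
  pva <- patch_xy(va)
  model2d <- train_classifier(ptr$x, ptr$y, pva$x, pva$y, config$training)
  heat_valid <- lapply(which(va), function(k) {
    p <- extraction$patch[[k]]
    p$patchset$patches$probability <- predict_probability(model2d, p$x)
    build_heatmap(p$patchset)
  })
  search <- search_area_threshold(heat_valid, extraction$truth[va],
                                  connectivity = config$connectivity)
  model3d <- train_classifier(extraction$x3d[tr, , drop = FALSE],
                              extraction$truth[tr],
                              extraction$x3d[va, , drop = FALSE],
                              extraction$truth[va], config$training)
  p3d_va <- predict_probability(model3d,
                                extraction$x3d[va, , drop = FALSE])
  area_va <- search$areas
  fusion <- if (config$fusion_source == "paper") paper_fusion_model()
            else fit_fusion(p3d_va, area_va, extraction$truth[va])
  pc_va <- combined_probability(fusion, p3d_va, area_va)
  cutoffs <- list(p3d = youden_cutoff(p3d_va, extraction$truth[va])$cutoff,
                  area2d = youden_cutoff(area_va,
                                         extraction$truth[va])$cutoff,
                  p_combined = youden_cutoff(pc_va,
                                             extraction$truth[va])$cutoff)
  structure(list(model2d = model2d, model3d = model3d,
                 area_threshold = search$threshold,
                 threshold_trace = search$grid,
                 fusion = fusion, cutoffs = cutoffs, config = config),
            class = "model_bundle")
}

#' @exportS3Method base::print
print.model_bundle <- function(x, ...) {
  cat("<model_bundle>\n  2D patch model: iteration ",
      x$model2d$selected_iteration, "\n  3D model: iteration ",
      x$model3d$selected_iteration, "\n  heatmap threshold: ",
      x$area_threshold, "\n  fusion: ", x$fusion$source,
      "\n  cutoffs: p3d > ", signif(x$cutoffs$p3d, 4), ", area > ",
      signif(x$cutoffs$area2d, 4), ", combined > ",
      signif(x$cutoffs$p_combined, 4), "\n", sep = "")
  invisible(x)
}

#' Persist / restore a model bundle
#'
#' Writes the two boosters (xgboost JSON), the area threshold and its
#' search trace, the fusion coefficients and the operating cutoffs into a
#' directory, so the exact operating point travels with the models.
#'
#' @param bundle a `model_bundle`.
#' @param dir output directory.
#' @return `save_bundle()` returns `dir`; `load_bundle()` the bundle (the
#'   pipeline configuration is not round-tripped: pass the one used at
#'   training time when re-scoring).
#' @export
save_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  save_classifier(bundle$model2d, file.path(dir, "model2d"))
  save_classifier(bundle$model3d, file.path(dir, "model3d"))
  op <- list(area_threshold = bundle$area_threshold,
             fusion = unclass(bundle$fusion)[c("intercept", "coef_p3d",
                                               "coef_area", "source")],
             cutoffs = bundle$cutoffs)
  jsonlite::write_json(op, file.path(dir, "operating_point.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(bundle$threshold_trace, file.path(dir, "threshold_trace.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' @rdname save_bundle
#' @param config the [pipeline_config()] used at training time.
#' @export
load_bundle <- function(dir, config = pipeline_config()) {
  op <- jsonlite::read_json(file.path(dir, "operating_point.json"),
                            simplifyVector = TRUE)
  fusion <- structure(list(intercept = op$fusion$intercept,
                           coef_p3d = op$fusion$coef_p3d,
                           coef_area = op$fusion$coef_area,
                           source = op$fusion$source),
                      class = "fusion_model")
  structure(list(model2d = load_classifier(file.path(dir, "model2d")),
                 model3d = load_classifier(file.path(dir, "model3d")),
                 area_threshold = op$area_threshold,
                 threshold_trace = read.csv(
                   file.path(dir, "threshold_trace.csv")),
                 fusion = fusion,
                 cutoffs = as.list(op$cutoffs), config = config),
            class = "model_bundle")
}

#' Score studies with a trained bundle
#'
#' @param bundle a `model_bundle`.
#' @param extraction an `extraction`.
#' @param sel logical/integer selection of studies (default all).
#' @return data.frame of per-study predictions and calls (see [decide()]).
#' @export
predict_studies <- function(bundle, extraction,
                            sel = seq_along(extraction$study_id)) {
  idx <- seq_along(extraction$study_id)[sel]
  p3d <- predict_probability(bundle$model3d,
                             extraction$x3d[idx, , drop = FALSE])
  area <- vapply(idx, function(k) {
    p <- extraction$patch[[k]]
    if (nrow(p$patchset$patches) == 0) return(0)
    p$patchset$patches$probability <- predict_probability(bundle$model2d,
                                                          p$x)
    largest_high_risk_area(build_heatmap(p$patchset),
                           bundle$area_threshold,
                           bundle$config$connectivity)$area_mm2
  }, 0)
  pc <- combined_probability(bundle$fusion, p3d, area)
  decide(p3d, area, pc, bundle$cutoffs,
         study_id = extraction$study_id[idx])
}

#' Evaluate a bundle on held-out studies
#'
#' Refuses to score studies that overlap the ids used in training.
#'
#' @param bundle a `model_bundle`.
#' @param extraction an `extraction` holding the test studies.
#' @param train_ids ids used for training/validation (overlap check).
#' @return A `diagnostic_report`.
#' @export
run_evaluate <- function(bundle, extraction, train_ids = character(0)) {
  if (length(extraction$study_id) == 0)
    stop_pancrad("empty test set", "pancrad_input_error")
  if (any(extraction$study_id %in% train_ids))
    stop_pancrad("test studies overlap the training set",
                 "pancrad_input_error")
  preds <- predict_studies(bundle, extraction)
  preds$truth <- extraction$truth
  preds$stratum <- extraction$stratum
  diagnostic_report(preds)
}

#' Cohort-level diagnostic report
#'
#' Accepts a per-study calls table — either from [predict_studies()] (plus
#' `truth`/`stratum` columns) or a bare calls CSV with columns `study_id`,
#' `truth`, `call3d`, `call2d` and optionally `call_combined`,
#' `call_series`, `call_parallel`, `p3d`, `area2d`, `p_combined`,
#' `stratum` — and computes, per analysis, sensitivity/specificity/accuracy
#' with exact CIs, likelihood ratios, AUCs (score-based analyses), the
#' four-cell cross-tab with per-cell LRs, and size-stratified sensitivity
#' with a trend test.
#'
#' @param calls data.frame as described.
#' @return A `diagnostic_report` list.
#' @export
diagnostic_report <- function(calls) {
  stopifnot(all(c("truth", "call3d", "call2d") %in% names(calls)))
  truth <- as_label01(calls$truth)
  if (is.null(calls$call_series))
    calls$call_series <- calls$call3d & calls$call2d
  if (is.null(calls$call_parallel))
    calls$call_parallel <- calls$call3d | calls$call2d
  analyses <- c("3d" = "call3d", "2d" = "call2d",
                combined = "call_combined",
                series = "call_series", parallel = "call_parallel")
  analyses <- analyses[unlist(analyses) %in% names(calls)]
  metrics <- list()
  lrs <- list()
  for (a in names(analyses)) {
    cc <- confusion_counts(calls[[analyses[[a]]]], truth)
    metrics[[a]] <- accuracy_metrics(cc)
    lrs[[a]] <- likelihood_ratios(cc)
  }
  scores <- c("3d" = "p3d", "2d" = "area2d", combined = "p_combined")
  scores <- scores[unlist(scores) %in% names(calls)]
  aucs <- lapply(scores, function(s) roc_auc(calls[[s]], truth))
  tab <- cross_tab(
    pc = c(sum(calls$call3d & calls$call2d & truth == 1),
           sum(calls$call3d & !calls$call2d & truth == 1),
           sum(!calls$call3d & calls$call2d & truth == 1),
           sum(!calls$call3d & !calls$call2d & truth == 1)),
    control = c(sum(calls$call3d & calls$call2d & truth == 0),
                sum(calls$call3d & !calls$call2d & truth == 0),
                sum(!calls$call3d & calls$call2d & truth == 0),
                sum(!calls$call3d & !calls$call2d & truth == 0)))
  strat <- NULL
  if (!is.null(calls$stratum) && any(truth == 1 & !is.na(calls$stratum))) {
    cases <- truth == 1 & !is.na(calls$stratum)
    strat <- lapply(analyses, function(col)
      size_stratified_sensitivity(calls[[col]][cases],
                                  calls$stratum[cases]))
  }
  structure(list(n_studies = nrow(calls), n_pc = sum(truth == 1),
                 n_control = sum(truth == 0), metrics = metrics,
                 likelihood_ratios = lrs, auc = aucs, cross_tab = tab,
                 stratum_lr = stratum_likelihood_ratios(tab),
                 size_stratified = strat, calls = calls),
            class = "diagnostic_report")
}

#' @exportS3Method base::print
print.diagnostic_report <- function(x, ...) {
  cat("Diagnostic report: ", x$n_pc, " PC / ", x$n_control,
      " control studies\n\n", sep = "")
  fmt <- function(ci) sprintf("%.3f (%.3f-%.3f)", ci$point, ci$lower,
                              ci$upper)
  for (a in names(x$metrics)) {
    m <- x$metrics[[a]]
    l <- x$likelihood_ratios[[a]]
    cat(sprintf("  %-9s sens %s  spec %s  acc %s", a,
                fmt(m[1, -1]), fmt(m[2, -1]), fmt(m[3, -1])))
    if (!is.null(x$auc[[a]])) cat("  AUC", fmt(x$auc[[a]]))
    cat(sprintf("  LR+ %.2f  LR- %.2f\n", l$point[1], l$point[2]))
  }
  cat("\n  Cross-tab LR per (3D, 2D) cell:\n")
  s <- x$stratum_lr
  for (i in seq_len(nrow(s)))
    cat(sprintf("    %-7s LR %.2f (%.2f-%.2f)\n", s$cell[i], s$point[i],
                s$lower[i], s$upper[i]))
  invisible(x)
}

#' Evaluate a bare calls table from CSV
#'
#' @param path CSV with the columns described in [diagnostic_report()].
#' @return A `diagnostic_report`.
#' @export
evaluate_calls_csv <- function(path) {
  diagnostic_report(read.csv(path, stringsAsFactors = FALSE))
}

#' Write a diagnostic report as JSON
#'
#' @param report a `diagnostic_report`.
#' @param path output JSON path.
#' @export
write_report_json <- function(report, path) {
  out <- report[setdiff(names(report), "calls")]
  out$cross_tab <- unclass(out$cross_tab)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' Seeded end-to-end phantom experiment
#'
#' Generates a training cohort of `n_train + n_valid` phantom studies and a
#' disjoint test cohort of `n_test` studies (half cases, half controls),
#' runs extraction, trains the full bundle and evaluates on the held-out
#' cohort. This is the package's standing demonstration that the combined
#' analysis learns the planted hypodense/heterogeneous tumor signal
#' end-to-end.
#'
#' @param seed root seed for cohorts and training.
#' @param n_train,n_valid,n_test split sizes (studies).
#' @param spec base [phantom_spec()]; composition fields are overridden.
#' @param config a [pipeline_config()].
#' @return list: `auc3d`, `auc2d`, `auc_combined` (test-set AUC rows),
#'   `report`, `bundle`.
#' @export
run_phantom_experiment <- function(seed = 1L, n_train = 90L, n_valid = 60L,
                                   n_test = 100L, spec = phantom_spec(),
                                   config = pipeline_config()) {
  config$seed <- as.integer(seed)
  config$training$seed <- derive_seed(seed, 101L)
  spec_tr <- spec
  spec_tr$n_cases <- as.integer((n_train + n_valid) / 2)
  spec_tr$n_controls <- as.integer(n_train + n_valid) - spec_tr$n_cases
  spec_tr$seed <- derive_seed(seed, 1L)
  spec_te <- spec
  spec_te$n_cases <- as.integer(n_test / 2)
  spec_te$n_controls <- as.integer(n_test) - spec_te$n_cases
  spec_te$seed <- derive_seed(seed, 2L)
  cohort_tr <- generate_cohort(spec_tr)
  cohort_te <- generate_cohort(spec_te)
  cohort_te$manifest$study_id <- paste0("test_", cohort_te$manifest$study_id)
  ex_tr <- run_extract(cohort_tr, config)
  ex_te <- run_extract(cohort_te, config)
  # alternate train/valid within each class so both splits stay balanced
  roles <- rep("train", length(ex_tr$study_id))
  for (cl in c(0, 1)) {
    idx <- which(ex_tr$truth == cl)
    n_va <- round(length(idx) * n_valid / (n_train + n_valid))
    roles[idx[seq_len(n_va)]] <- "valid"
  }
  bundle <- run_train(ex_tr, roles, config)
  report <- run_evaluate(bundle, ex_te, train_ids = ex_tr$study_id)
  list(auc3d = report$auc[["3d"]], auc2d = report$auc[["2d"]],
       auc_combined = report$auc[["combined"]], report = report,
       bundle = bundle)
}
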