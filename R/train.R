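# Gradient-boosted tree classifiers (patch-level 2D, study-level 3D):
# logistic loss, validation-AUC early stopping with a 30-round patience,
# and the iteration with the highest validation AUC selected as the final
# model. Booster hyperparameters are unexceptional defaults (depth 6,
# learning rate 0.1, no subsampling) and are recorded in the model metadata.

#' Training configuration
#'
#' @param max_rounds maximum boosting rounds (default 1000).
#' @param early_stop_patience rounds without validation-AUC improvement
#'   before stopping (default 30).
#' @param eta learning rate (default 0.1).
#' @param max_depth tree depth (default 6).
#' @param subsample row subsampling fraction (default 1, none).
#' @param scale_pos_weight positive-class weight (default 1; class
#'   imbalance is not reweighted unless requested).
#' @param nthread threads (default 1 for reproducibility).
#' @param seed RNG seed recorded in the model metadata.
#' @return A `training_config` list.
#' @export
training_config <- function(max_rounds = 1000L, early_stop_patience = 30L,
                            eta = 0.1, max_depth = 6L, subsample = 1,
                            scale_pos_weight = 1, nthread = 1L, seed = 0L) {
  structure(list(max_rounds = as.integer(max_rounds),
                 early_stop_patience = as.integer(early_stop_patience),
                 eta = eta, max_depth = as.integer(max_depth),
                 subsample = subsample, scale_pos_weight = scale_pos_weight,
                 nthread = as.integer(nthread), seed = as.integer(seed)),
            class = "training_config")
}

#' Train a boosted-tree classifier with validation-AUC early stopping
#'
#' @param x_train,x_valid numeric feature matrices with identical column
#'   names; rows are patches (2D branch) or studies (3D branch).
#' @param y_train,y_valid binary labels (1 = cancerous).
#' @param config a [training_config()].
#' @return A `pancrad_classifier`: the booster, the selected iteration
#'   (argmax of the validation-AUC trace), the full per-iteration AUC log,
#'   the fit-time feature order and the configuration.
#' @export
train_classifier <- function(x_train, y_train, x_valid, y_valid,
                             config = training_config()) {
  y_train <- as_label01(y_train)
  y_valid <- as_label01(y_valid)
  if (length(unique(y_train)) < 2 || length(unique(y_valid)) < 2)
    stop_pancrad("both classes must be present in train and validation",
                 "pancrad_training_error")
  if (anyNA(x_train) || anyNA(x_valid))
    stop_pancrad("feature matrices contain missing values",
                 "pancrad_validation_error")
  if (!identical(colnames(x_train), colnames(x_valid)))
    stop_pancrad("train/validation feature names differ",
                 "pancrad_schema_error")
  set.seed(config$seed)
  dtrain <- xgboost::xgb.DMatrix(as.matrix(x_train), label = y_train,
                                 nthread = config$nthread)
  dvalid <- xgboost::xgb.DMatrix(as.matrix(x_valid), label = y_valid,
                                 nthread = config$nthread)
  params <- list(objective = "binary:logistic", eval_metric = "auc",
                 eta = config$eta, max_depth = config$max_depth,
                 subsample = config$subsample,
                 scale_pos_weight = config$scale_pos_weight,
                 nthread = config$nthread, seed = config$seed)
  bst <- xgboost::xgb.train(params = params, data = dtrain,
                            nrounds = config$max_rounds,
                            evals = list(valid = dvalid),
                            early_stopping_rounds =
                              config$early_stop_patience,
                            maximize = TRUE, verbose = 0)
  log <- as.data.frame(attributes(bst)$evaluation_log)
  names(log) <- c("iteration", "valid_auc")
  best <- which.max(log$valid_auc)   # first maximum
  structure(list(booster = bst,
                 selected_iteration = best,
                 eval_log = log,
                 feature_names = colnames(x_train),
                 config = config),
            class = "pancrad_classifier")
}

#' @exportS3Method base::print
print.pancrad_classifier <- function(x, ...) {
  cat("<pancrad_classifier> ", length(x$feature_names), " features, ",
      nrow(x$eval_log), " rounds trained, iteration ",
      x$selected_iteration, " selected (valid AUC ",
      round(x$eval_log$valid_auc[x$selected_iteration], 4), ")\n", sep = "")
  invisible(x)
}

#' Predict cancer probabilities
#'
#' Scores rows with the selected (highest validation AUC) iteration.
#' Feature names and order must match the fit.
#'
#' @param model a `pancrad_classifier`.
#' @param x numeric feature matrix.
#' @return Numeric vector of probabilities in \[0, 1\], one per row.
#' @export
predict_probability <- function(model, x) {
  stopifnot(inherits(model, "pancrad_classifier"))
  x <- as.matrix(x)
  if (nrow(x) == 0) return(numeric(0))
  if (!identical(colnames(x), model$feature_names))
    stop_pancrad("feature names/order do not match the fitted model",
                 "pancrad_schema_error")
  as.numeric(predict(model$booster, x,
                     iterationrange = c(1, model$selected_iteration)))
}

#' Gain-based feature ranking
#'
#' Total split gain accumulated by each feature over the selected ensemble,
#' sorted non-increasing. Features never used in a split are absent.
#'
#' @param model a `pancrad_classifier`.
#' @return data.frame with columns `feature` and `gain`.
#' @export
feature_gain_ranking <- function(model) {
  stopifnot(inherits(model, "pancrad_classifier"))
  tr <- xgboost::xgb.model.dt.tree(model = model$booster)
  tr <- as.data.frame(tr)
  tr <- tr[tr$Feature != "Leaf" & tr$Tree < model$selected_iteration, ]
  if (nrow(tr) == 0)
    return(data.frame(feature = character(0), gain = numeric(0)))
  g <- tapply(tr$Gain, tr$Feature, sum)
  out <- data.frame(feature = names(g), gain = as.numeric(g))
  out <- out[order(-out$gain), ]
  rownames(out) <- NULL
  out
}

#' Persist / restore a trained classifier
#'
#' The booster is stored in xgboost's JSON format next to a metadata JSON
#' holding the feature schema, selected iteration, evaluation log and
#' configuration, so schema drift is detected at load/predict time.
#'
#' @param model a `pancrad_classifier`.
#' @param path file stem; writes `<path>.model.json` and `<path>.meta.json`.
#' @return `save_classifier()` returns `path`; `load_classifier()` the model.
#' @export
save_classifier <- function(model, path) {
  xgboost::xgb.save(model$booster, paste0(path, ".model.json"))
  meta <- list(selected_iteration = model$selected_iteration,
               eval_log = model$eval_log,
               feature_names = model$feature_names,
               config = unclass(model$config))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  bst <- xgboost::xgb.load(paste0(path, ".model.json"))
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  structure(list(booster = bst,
                 selected_iteration = meta$selected_iteration,
                 eval_log = as.data.frame(meta$eval_log),
                 feature_names = meta$feature_names,
                 config = do.call(training_config, as.list(meta$config))),
            class = "pancrad_classifier")
}
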