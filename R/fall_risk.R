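# Random-forest fall-risk classification from 248-entry participant
# vectors, with stratified participant-level cross-validation.

#' Fall-risk dataset
#'
#' @param features matrix or data.frame, one row per participant, the 248
#'   columns of [participant_feature_names()] (any numeric feature matrix is
#'   accepted; the 248-name layout is the pipeline's).
#' @param labels logical (TRUE = fall risk: at least one self-reported fall
#'   in the prior six months) or factor with levels `fall_risk`,
#'   `no_fall_risk`.
#' @param provenance `"manual_fs"` or `"automated_fs"`: which foot-strike
#'   source produced the features.
#' @return a `fall_risk_dataset`.
#' @export
fall_risk_dataset <- function(features, labels,
                              provenance = c("manual_fs", "automated_fs")) {
  provenance <- match.arg(provenance)
  features <- as.matrix(features)
  if (is.logical(labels)) {
    labels <- factor(ifelse(labels, "fall_risk", "no_fall_risk"),
                     levels = c("fall_risk", "no_fall_risk"))
  }
  labels <- factor(labels, levels = c("fall_risk", "no_fall_risk"))
  if (anyNA(labels)) validation_error("labels must not contain missing values")
  if (nrow(features) != length(labels)) {
    validation_error("features and labels must have the same length")
  }
  structure(list(features = features, labels = labels,
                 provenance = provenance),
            class = "fall_risk_dataset")
}

#' Random-forest configuration for fall-risk classification
#'
#' The published protocol does not state hyperparameters; these defaults
#' (500 trees, unlimited depth, inverse-frequency class weights, stratified
#' 5-fold CV) are this package's documented choices.
#'
#' @param n_trees number of trees.
#' @param max_depth maximum tree depth, or `NULL` for unlimited.
#' @param class_weighting `"inverse_frequency"` or `"none"`.
#' @param cv_folds folds for [evaluate_fall_risk()].
#' @param seed integer seed (forest growth and fold assignment).
#' @return an `rf_config` object.
#' @export
rf_config <- function(n_trees = 500, max_depth = NULL,
                      class_weighting = c("inverse_frequency", "none"),
                      cv_folds = 5, seed = 1) {
  class_weighting <- match.arg(class_weighting)
  if (!is_count(n_trees)) validation_error("n_trees must be >= 1")
  if (!is_count(cv_folds) || cv_folds < 2) validation_error("cv_folds must be >= 2")
  structure(list(n_trees = as.integer(n_trees), max_depth = max_depth,
                 class_weighting = class_weighting,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "rf_config")
}

impute_medians <- function(x, medians = NULL) {
  if (is.null(medians)) {
    medians <- apply(x, 2, function(v) stats::median(v[is.finite(v)]))
    medians[!is.finite(medians)] <- 0
  }
  for (j in seq_len(ncol(x))) {
    bad <- !is.finite(x[, j])
    if (any(bad)) x[bad, j] <- medians[j]
  }
  list(x = x, medians = medians)
}

rf_class_weights <- function(labels, scheme) {
  if (scheme != "inverse_frequency") return(c(1, 1))
  tab <- table(labels)
  as.numeric(length(labels) / (2 * tab[c("fall_risk", "no_fall_risk")]))
}

#' Train the fall-risk random forest
#'
#' Undefined feature entries are imputed with training-set column medians
#' (stored on the handle and reused at prediction time). Deterministic given
#' the config seed.
#'
#' @param data a [fall_risk_dataset()].
#' @param config an [rf_config()].
#' @return a `fall_risk_model` handle.
#' @export
train_fall_risk <- function(data, config = rf_config()) {
  if (nlevels(droplevels(data$labels)) < 2L) {
    validation_error("training data must contain both classes")
  }
  imp <- impute_medians(data$features)
  df <- as.data.frame(imp$x)
  names(df) <- paste0("f", seq_len(ncol(df)))
  rf <- ranger::ranger(
    x = df, y = data$labels,
    num.trees = config$n_trees,
    max.depth = if (is.null(config$max_depth)) 0 else config$max_depth,
    class.weights = rf_class_weights(data$labels, config$class_weighting),
    seed = config$seed, num.threads = 1)
  structure(list(rf = rf, medians = imp$medians, config = config,
                 provenance = data$provenance),
            class = "fall_risk_model")
}

#' Predict fall-risk labels
#'
#' @param model a `fall_risk_model`.
#' @param features participant feature matrix (same columns as training).
#' @return factor with levels `fall_risk`, `no_fall_risk`.
#' @export
predict_fall_risk <- function(model, features) {
  x <- impute_medians(as.matrix(features), model$medians)$x
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(df)))
  stats::predict(model$rf, data = df, num.threads = 1)$predictions
}

#' Cross-validated fall-risk evaluation
#'
#' Stratified participant-level k-fold CV: folds preserve class proportions,
#' imputation medians come from each training fold only (no leakage), and
#' out-of-fold predictions are pooled into one confusion matrix with rows =
#' true class (fall risk first).
#'
#' @param data a [fall_risk_dataset()].
#' @param config an [rf_config()].
#' @return list with `confusion` (`confusion_matrix`), `metrics`
#'   (accuracy/sensitivity/specificity/precision, percent), `fold_assignment`,
#'   `predictions`, `seed`.
#' @export
evaluate_fall_risk <- function(data, config = rf_config()) {
  n <- length(data$labels)
  k <- config$cv_folds
  if (min(table(data$labels)) < k) {
    stop_stridetect(
      "each class needs at least as many participants as folds",
      "stridetect_stratification_error")
  }
  fold <- integer(n)
  for (cl in levels(data$labels)) {
    i <- which(data$labels == cl)
    fold[i] <- with_seed(config$seed + match(cl, levels(data$labels)),
                         sample(rep_len(seq_len(k), length(i))))
  }
  preds <- factor(rep(NA_character_, n),
                  levels = c("fall_risk", "no_fall_risk"))
  for (f in seq_len(k)) {
    tr <- fold != f
    sub <- fall_risk_dataset(data$features[tr, , drop = FALSE],
                             data$labels[tr], data$provenance)
    model <- train_fall_risk(sub, config)
    preds[!tr] <- predict_fall_risk(model, data$features[!tr, , drop = FALSE])
  }
  truth_pos <- data$labels == "fall_risk"
  pred_pos <- preds == "fall_risk"
  cm <- confusion_matrix(sum(truth_pos & pred_pos),
                         sum(truth_pos & !pred_pos),
                         sum(!truth_pos & pred_pos),
                         sum(!truth_pos & !pred_pos))
  list(confusion = cm, metrics = compute_metrics(cm),
       fold_assignment = fold, predictions = preds, seed = config$seed)
}
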