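# Tolerance-matched event evaluation and confusion-matrix metrics.

#' Confusion matrix of event or participant classification
#'
#' @param tp,fn,fp,tn non-negative integer counts.
#' @return a `confusion_matrix` object.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  v <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(!is.finite(v)) || any(v < 0) || any(v != floor(v))) {
    validation_error("confusion matrix counts must be non-negative integers")
  }
  v <- stats::setNames(as.integer(v), names(v))
  structure(as.list(v), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, byrow = TRUE,
              dimnames = list(c("true positive", "true negative"),
                              c("pred positive", "pred negative")))
  print(m)
  invisible(x)
}

#' Elementwise sum of confusion matrices
#' @param ... `confusion_matrix` objects.
#' @return pooled `confusion_matrix`.
#' @export
pool_confusion <- function(...) {
  ms <- list(...)
  if (length(ms) == 1L && is.list(ms[[1]]) && !inherits(ms[[1]], "confusion_matrix")) {
    ms <- ms[[1]]
  }
  confusion_matrix(sum(vapply(ms, `[[`, 0, "tp")),
                   sum(vapply(ms, `[[`, 0, "fn")),
                   sum(vapply(ms, `[[`, 0, "fp")),
                   sum(vapply(ms, `[[`, 0, "tn")))
}

#' Match predicted events to ground truth within a frame tolerance
#'
#' Maximum one-to-one matching of two ordered event-index sets under
#' `|truth - pred| <= tolerance`, computed by a two-pointer sweep (provably
#' maximum for interval matching on a line; ties resolved toward the earlier
#' truth index). Unmatched truths are false negatives, unmatched predictions
#' false positives, and every remaining sample a true negative.
#'
#' @param truth,pred `foot_strike_labels` or integer index vectors.
#' @param tolerance matching tolerance in frames (>= 0).
#' @param total total number of samples in the recording.
#' @return a `confusion_matrix`.
#' @export
match_with_tolerance <- function(truth, pred, tolerance = 2, total) {
  if (!is.numeric(tolerance) || tolerance < 0) {
    validation_error("tolerance must be >= 0")
  }
  ti <- as_fs_indices(truth); pi <- as_fs_indices(pred)
  if ((length(ti) && (min(ti) < 1 || max(ti) > total)) ||
      (length(pi) && (min(pi) < 1 || max(pi) > total))) {
    validation_error("event indices must lie within [1, total]")
  }
  i <- 1L; j <- 1L; tp <- 0L
  nt <- length(ti); np <- length(pi)
  while (i <= nt && j <= np) {
    if (abs(ti[i] - pi[j]) <= tolerance) {
      tp <- tp + 1L; i <- i + 1L; j <- j + 1L
    } else if (ti[i] < pi[j]) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  fn <- nt - tp; fp <- np - tp
  confusion_matrix(tp, fn, fp, total - tp - fn - fp)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, sensitivity (recall of the positive class), specificity, and
#' precision as percentages, rounded half-up to `digits` decimals for
#' reporting. A metric whose denominator is zero is `NA` (undefined), never
#' zero.
#'
#' @param cm a `confusion_matrix`.
#' @param digits decimals for half-up rounding; `NULL` for unrounded values.
#' @return a `classification_metrics` object (named list of percentages).
#' @export
compute_metrics <- function(cm, digits = 1) {
  tp <- cm$tp; fn <- cm$fn; fp <- cm$fp; tn <- cm$tn
  total <- tp + fn + fp + tn
  if (total <= 0) validation_error("confusion matrix total must be positive")
  frac <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  m <- c(accuracy = frac(tp + tn, total),
         sensitivity = frac(tp, tp + fn),
         specificity = frac(tn, tn + fp),
         precision = frac(tp, tp + fp))
  if (!is.null(digits)) m <- round_half_up(m, digits)
  structure(as.list(m), class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("accuracy %s  sensitivity %s  specificity %s  precision %s\n",
              format(x$accuracy), format(x$sensitivity),
              format(x$specificity), format(x$precision)))
  invisible(x)
}

#' Participant-level k-fold cross-validation of the foot-strike detector
#'
#' Trials are partitioned at the participant level (no trial contributes
#' windows to more than one fold). For each fold a model is trained on the
#' remaining trials and evaluated per held-out trial by tolerance matching;
#' fold matrices are summed into a pooled matrix.
#'
#' @param trials list of `list(windows = window_set, truth = foot_strike_labels)`.
#' @param k number of folds (>= 2, <= number of trials).
#' @param config an [fs_model_config()].
#' @param tolerance matching tolerance in frames.
#' @param postprocess apply [postprocess_predictions()] to each trial's
#'   predictions before matching.
#' @param pp_params [postprocess_params()] used when `postprocess` is TRUE.
#' @param detector optional replacement detector
#'   `function(train_trials, test_windows) -> foot_strike_labels`, e.g. an
#'   oracle in tests; when given, no model is trained.
#' @return list with `fold_matrices`, `fold_metrics`, `pooled_matrix`,
#'   `pooled_metrics`, `fold_assignment`.
#' @export
cross_validate <- function(trials, k = 5, config = fs_model_config(),
                           tolerance = 2, postprocess = TRUE,
                           pp_params = postprocess_params(),
                           detector = NULL) {
  n <- length(trials)
  if (!is_count(k) || k < 2) validation_error("k must be an integer >= 2")
  if (n < k) validation_error("need at least as many trials as folds")
  fold <- with_seed(config$seed, sample(rep_len(seq_len(k), n)))
  fold_ms <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    model <- NULL
    if (is.null(detector)) {
      model <- train_fs_model(lapply(trials[train_idx], `[[`, "windows"),
                              config)
    }
    cms <- lapply(test_idx, function(i) {
      ws <- trials[[i]]$windows
      pred <- if (is.null(detector)) {
        predict_fs(model, ws)
      } else {
        detector(trials[train_idx], ws)
      }
      if (postprocess) {
        pred <- postprocess_predictions(pred, center_signal(ws, "ap"),
                                        ws$rate, pp_params)
      }
      match_with_tolerance(trials[[i]]$truth, pred, tolerance,
                           total = length(ws$labels))
    })
    fold_ms[[f]] <- pool_confusion(cms)
  }
  pooled <- pool_confusion(fold_ms)
  list(fold_matrices = fold_ms,
       fold_metrics = lapply(fold_ms, compute_metrics),
       pooled_matrix = pooled,
       pooled_metrics = compute_metrics(pooled),
       fold_assignment = fold)
}
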