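# Rule-based correction of predicted foot strikes: consolidate runs of
# consecutive per-sample predictions into one event at the AP acceleration
# peak, then fill abnormally long inter-strike gaps by inserting a strike at
# the AP peak inside an adaptive locking window.

#' Post-processing parameters
#'
#' @param gap_factor a gap qualifies for insertion when it exceeds
#'   `gap_factor` times the previous step duration (default 1.5).
#' @param locking_margin fraction of the previous step duration excluded at
#'   each end of a qualifying gap before searching for the missed strike's
#'   AP peak; keeps insertions from crowding existing strikes (refractory
#'   logic). Must be in [0, 0.5).
#' @param max_passes upper bound on re-scan passes (a gap hiding several
#'   missed steps is filled one insertion per pass).
#' @return a `postprocess_params` object.
#' @export
postprocess_params <- function(gap_factor = 1.5, locking_margin = 0.4,
                               max_passes = 6) {
  if (!is.numeric(gap_factor) || gap_factor <= 1) {
    validation_error("gap_factor must be > 1")
  }
  if (!is.numeric(locking_margin) || locking_margin < 0 || locking_margin >= 0.5) {
    validation_error("locking_margin must be in [0, 0.5)")
  }
  if (!is_count(max_passes)) validation_error("max_passes must be a positive integer")
  structure(list(gap_factor = gap_factor, locking_margin = locking_margin,
                 max_passes = as.integer(max_passes)),
            class = "postprocess_params")
}

#' Consolidate runs of consecutive predictions
#'
#' Each maximal run of consecutive indices is replaced by the single index of
#' maximum AP acceleration within the run; isolated predictions pass through.
#'
#' @param pred `foot_strike_labels` or integer indices.
#' @param ap_signal per-sample AP acceleration (m/s^2).
#' @return `foot_strike_labels` with `source = "postprocessed"`.
#' @export
consolidate_runs <- function(pred, ap_signal) {
  idx <- as_fs_indices(pred)
  if (length(idx) && max(idx) > length(ap_signal)) {
    validation_error("prediction indices exceed signal length")
  }
  if (length(idx) < 2L) {
    return(foot_strike_labels(idx, "postprocessed", length(ap_signal)))
  }
  run_id <- cumsum(c(1L, diff(idx) != 1L))
  keep <- vapply(split(idx, run_id), function(run) {
    run[which.max(ap_signal[run])]
  }, integer(1))
  foot_strike_labels(sort(unname(keep)), "postprocessed", length(ap_signal))
}

#' Insert missed steps inside adaptive locking windows
#'
#' Scans strikes left to right; an inter-strike gap longer than
#' `gap_factor` times the previous step duration gets one strike inserted at
#' the AP acceleration argmax of the gap interior, after excluding
#' `locking_margin` times the previous step duration at each end. The scan
#' repeats (gaps spanning several missed steps fill incrementally) until no
#' gap qualifies or `max_passes` is reached. The previous step duration for
#' the first gap is the trial's median step duration.
#'
#' @param pred `foot_strike_labels` or integer indices (run-consolidated).
#' @param ap_signal per-sample AP acceleration.
#' @param rate sampling rate, Hz.
#' @param params a [postprocess_params()].
#' @return `foot_strike_labels` with `source = "postprocessed"`; existing
#'   predictions are never removed. With fewer than 2 predictions the input
#'   is returned unchanged with a warning.
#' @export
insert_missed_steps <- function(pred, ap_signal, rate,
                                params = postprocess_params()) {
  idx <- as_fs_indices(pred)
  if (length(idx) < 2L) {
    warning("fewer than 2 predictions; nothing to scan for missed steps")
    return(foot_strike_labels(idx, "postprocessed", length(ap_signal)))
  }
  for (pass in seq_len(params$max_passes)) {
    durs <- diff(idx)
    med <- stats::median(durs)
    inserted <- integer(0)
    for (j in seq_along(durs)) {
      prev <- if (j == 1L) med else idx[j] - idx[j - 1L]
      gap <- durs[j]
      if (gap <= params$gap_factor * prev) next
      margin <- params$locking_margin * prev
      lo <- ceiling(idx[j] + margin)
      hi <- floor(idx[j + 1L] - margin)
      lo <- max(lo, idx[j] + 1L)
      hi <- min(hi, idx[j + 1L] - 1L)
      if (lo > hi) next
      win <- lo:hi
      inserted <- c(inserted, win[which.max(ap_signal[win])])
    }
    if (!length(inserted)) break
    idx <- sort(unique(c(idx, inserted)))
  }
  foot_strike_labels(idx, "postprocessed", length(ap_signal))
}

#' Full prediction post-processing
#'
#' [consolidate_runs()] followed by [insert_missed_steps()]; idempotent on
#' its own output.
#'
#' @inheritParams insert_missed_steps
#' @return `foot_strike_labels` with `source = "postprocessed"`.
#' @export
postprocess_predictions <- function(pred, ap_signal, rate,
                                    params = postprocess_params()) {
  out <- consolidate_runs(pred, ap_signal)
  if (length(out$indices) < 2L) return(out)
  insert_missed_steps(out, ap_signal, rate, params)
}
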