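# Stride parameters from foot-strike sequences and comparison against
# minimal-detectable-change thresholds.

#' Minimal detectable change thresholds for stride parameters
#'
#' Defaults are published healthy-older-adult values (no amputee-specific
#' MDC exists): step time 0.042 s, stride time 0.772 s, cadence 8.44
#' steps/min.
#'
#' @param step_time,stride_time,cadence positive thresholds.
#' @return an `mdc_thresholds` object.
#' @export
mdc_thresholds <- function(step_time = 0.042, stride_time = 0.772,
                           cadence = 8.44) {
  for (v in c(step_time, stride_time, cadence)) {
    if (!is_pos(v)) validation_error("MDC thresholds must be positive")
  }
  structure(list(step_time = step_time, stride_time = stride_time,
                 cadence = cadence), class = "mdc_thresholds")
}

# Alternating foot assignment. "auto" infers the first foot from the sign of
# medio-lateral acceleration at the strikes, assuming +ML at right-foot
# strikes (the pelvis sways toward the stance side); override explicitly if
# the sensor convention differs.
assign_feet <- function(n, first_foot, ml_at_strikes = NULL) {
  if (first_foot == "auto") {
    if (is.null(ml_at_strikes)) {
      precondition_error("first_foot = 'auto' needs the ML signal at strikes")
    }
    alt <- rep_len(c(1, -1), n)
    first_foot <- if (sum(ml_at_strikes * alt) >= 0) "right" else "left"
  }
  other <- if (first_foot == "right") "left" else "right"
  rep_len(c(first_foot, other), n)
}

#' Stride parameters from a foot-strike sequence
#'
#' Step time is the interval between consecutive strikes (attributed to the
#' striking foot), stride time the interval between consecutive same-foot
#' strikes, cadence `(n_strikes - 1) / elapsed * 60` (unbiased on partial
#' windows: n strikes delimit n-1 steps).
#'
#' @param fs `foot_strike_labels` or integer indices (>= 3 strikes).
#' @param rate sampling rate, Hz.
#' @param first_foot `"left"`, `"right"`, or `"auto"` (see Details in
#'   `assign_feet`: auto uses the ML acceleration sign at the strikes).
#' @param ml_signal per-sample medio-lateral acceleration, required for
#'   `"auto"`.
#' @return a `stride_parameters` object: `step_times` (data.frame `time`,
#'   `foot`, `step_time`), `stride_times`, `cadence`, and a `summary` list of
#'   means and SDs (overall and per foot).
#' @export
compute_stride_parameters <- function(fs, rate, first_foot = c("auto", "left", "right"),
                                      ml_signal = NULL) {
  first_foot <- match.arg(first_foot)
  idx <- as_fs_indices(fs)
  if (length(idx) < 3L) {
    validation_error("need at least 3 foot strikes for stride parameters")
  }
  times <- (idx - 1) / rate
  feet <- assign_feet(length(idx), first_foot,
                      if (!is.null(ml_signal)) ml_signal[idx])
  step_times <- diff(times)
  step_feet <- feet[-1]                    # step ends at (is attributed to) its strike
  stride_times <- times[-(1:2)] - times[seq_len(length(times) - 2L)]
  elapsed <- times[length(times)] - times[1]
  cadence <- (length(idx) - 1) / elapsed * 60
  s <- function(v) list(mean = mean(v), sd = stats::sd(v))
  structure(list(
    strike_times = times, feet = feet,
    step_times = data.frame(time = times[-1], foot = step_feet,
                            step_time = step_times),
    stride_times = stride_times, cadence = cadence,
    summary = list(
      step_time = s(step_times),
      step_time_left = s(step_times[step_feet == "left"]),
      step_time_right = s(step_times[step_feet == "right"]),
      stride_time = s(stride_times),
      cadence = cadence)),
    class = "stride_parameters")
}

#' @export
print.stride_parameters <- function(x, ...) {
  cat(sprintf(
    "<stride_parameters> %d strikes: step %.3f (%.3f) s, stride %.3f (%.3f) s, cadence %.1f steps/min\n",
    length(x$strike_times), x$summary$step_time$mean, x$summary$step_time$sd,
    x$summary$stride_time$mean, x$summary$stride_time$sd, x$cadence))
  invisible(x)
}

#' Compare manual vs automated stride parameters against MDC thresholds
#'
#' @param manual,auto `stride_parameters` computed on the same recording
#'   span from manual and automated foot strikes.
#' @param mdc an [mdc_thresholds()].
#' @return data.frame with one row per parameter: `manual`, `automated`,
#'   `difference` (automated - manual), `mdc`, `within_mdc`.
#' @export
compare_to_mdc <- function(manual, auto, mdc = mdc_thresholds()) {
  rows <- list(
    step_time = c(manual$summary$step_time$mean, auto$summary$step_time$mean,
                  mdc$step_time),
    stride_time = c(manual$summary$stride_time$mean,
                    auto$summary$stride_time$mean, mdc$stride_time),
    cadence = c(manual$cadence, auto$cadence, mdc$cadence))
  out <- do.call(rbind, lapply(names(rows), function(p) {
    v <- rows[[p]]
    data.frame(parameter = p, manual = v[1], automated = v[2],
               difference = v[2] - v[1], mdc = v[3],
               within_mdc = abs(v[2] - v[1]) <= v[3])
  }))
  rownames(out) <- NULL
  out
}
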