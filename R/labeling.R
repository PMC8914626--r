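# Deterministic ground-truth labelling heuristic: a foot strike is an
# anterior-posterior acceleration peak followed shortly by a vertical
# acceleration peak. This stands in for the human raters' procedure (graph
# inspection plus video confirmation), which the pipeline cannot reproduce.

#' Parameters of the foot-strike labelling heuristic
#'
#' @param ap_prominence_min minimum prominence (m/s^2) of an AP peak to be a
#'   strike candidate.
#' @param vert_prominence_min minimum prominence (m/s^2) of the confirming
#'   vertical peak.
#' @param max_vert_lag maximum delay (s) of the vertical peak after the AP
#'   peak; 0.25 s sits inside a typical loading-response interval and below
#'   any plausible step time.
#' @param min_step_separation minimum spacing (s) between labelled strikes;
#'   closer candidates are resolved in favour of the larger AP peak.
#' @return a `labeling_params` object.
#' @export
labeling_params <- function(ap_prominence_min = 0.8,
                            vert_prominence_min = 0.4,
                            max_vert_lag = 0.25,
                            min_step_separation = 0.3) {
  for (v in c(ap_prominence_min, vert_prominence_min, max_vert_lag,
              min_step_separation)) {
    if (!is_pos(v)) validation_error("all labeling parameters must be positive")
  }
  structure(list(ap_prominence_min = ap_prominence_min,
                 vert_prominence_min = vert_prominence_min,
                 max_vert_lag = max_vert_lag,
                 min_step_separation = min_step_separation),
            class = "labeling_params")
}

#' Local maxima with prominences
#'
#' A local maximum is strictly higher than its left neighbour and at least as
#' high as its right neighbour (plateaus yield their first sample). The
#' prominence of a peak is its height above the higher of the two lowest
#' points separating it from higher terrain on each side (the vector edge
#' counts as terrain when no higher peak exists on that side).
#'
#' @param x numeric vector.
#' @return list with integer `indices` and numeric `prominences`.
#' @export
find_peaks <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(indices = integer(0), prominences = numeric(0)))
  left <- c(-Inf, x[-n])
  right <- c(x[-1], -Inf)
  idx <- which(x > left & x >= right)
  idx <- idx[idx > 1L & idx < n]
  prom <- vapply(idx, function(i) {
    h <- x[i]
    lmin <- h
    j <- i
    while (j > 1L) {
      j <- j - 1L
      if (x[j] > h) break
      if (x[j] < lmin) lmin <- x[j]
    }
    rmin <- h
    j <- i
    while (j < n) {
      j <- j + 1L
      if (x[j] > h) break
      if (x[j] < rmin) rmin <- x[j]
    }
    h - max(lmin, rmin)
  }, numeric(1))
  list(indices = idx, prominences = prom)
}

#' Label foot strikes from AP and vertical acceleration peaks
#'
#' Implements the labelling rule: candidate strikes are AP local maxima with
#' prominence at least `ap_prominence_min` that are followed within
#' `(0, max_vert_lag]` by a vertical local maximum with prominence at least
#' `vert_prominence_min`. Candidates closer than `min_step_separation` are
#' thinned iteratively, keeping the larger AP peak. Requires a filtered,
#' uniformly sampled recording.
#'
#' @param rec a uniformly sampled `imu_recording` (filter first; raw signals
#'   produce spurious prominence peaks).
#' @param params a [labeling_params()] object.
#' @return `foot_strike_labels` with `source = "ground_truth"`.
#' @export
label_foot_strikes <- function(rec, params = labeling_params()) {
  if (!inherits(rec, "imu_recording")) validation_error("rec must be an imu_recording")
  if (!is_uniform(rec)) {
    precondition_error("recording must be uniformly sampled (resample first)")
  }
  rate <- 1 / mean(diff(rec$timestamps))
  ap <- channel(rec, "ap")
  vert <- channel(rec, "vert")

  app <- find_peaks(ap)
  cand <- app$indices[app$prominences >= params$ap_prominence_min]
  vp <- find_peaks(vert)
  vidx <- vp$indices[vp$prominences >= params$vert_prominence_min]
  if (length(cand) && length(vidx)) {
    max_lag <- params$max_vert_lag * rate
    has_vert <- vapply(cand, function(i) {
      any(vidx > i & vidx <= i + max_lag)
    }, logical(1))
    cand <- cand[has_vert]
  } else {
    cand <- integer(0)
  }

  # resolve candidates closer than the minimum step separation in favour of
  # the larger AP value, repeating until stable
  min_gap <- params$min_step_separation * rate
  while (length(cand) >= 2L) {
    gaps <- diff(cand)
    close <- which(gaps < min_gap)
    if (!length(close)) break
    j <- close[1]
    drop <- if (ap[cand[j]] >= ap[cand[j + 1L]]) j + 1L else j
    cand <- cand[-drop]
  }
  foot_strike_labels(cand, "ground_truth", n_total = n_samples(rec))
}
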