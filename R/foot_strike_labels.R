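# Foot-strike label container and helpers.

#' Foot-strike labels
#'
#' Ordered 1-based sample indices of foot-strike events over a recording.
#'
#' @param indices integer sample indices, strictly increasing.
#' @param source one of `"ground_truth"`, `"model"`, `"postprocessed"`.
#' @param n_total optional recording length the indices must fit in.
#' @return a `foot_strike_labels` object.
#' @export
foot_strike_labels <- function(indices,
                               source = c("ground_truth", "model", "postprocessed"),
                               n_total = NULL) {
  source <- match.arg(source)
  indices <- as.integer(indices)
  if (length(indices)) {
    if (any(indices < 1L)) validation_error("indices must be >= 1")
    if (any(diff(indices) <= 0L)) {
      validation_error("indices must be strictly increasing")
    }
    if (!is.null(n_total) && indices[length(indices)] > n_total) {
      validation_error("indices exceed recording length")
    }
  }
  structure(list(indices = indices, source = source), class = "foot_strike_labels")
}

#' @export
print.foot_strike_labels <- function(x, ...) {
  cat(sprintf("<foot_strike_labels> %d events (%s)\n",
              length(x$indices), x$source))
  invisible(x)
}

as_fs_indices <- function(x) {
  if (inherits(x, "foot_strike_labels")) x$indices else as.integer(x)
}

#' Expand foot-strike labels into a per-sample binary vector
#'
#' @param labels a `foot_strike_labels` object or integer index vector.
#' @param length total number of samples.
#' @return integer vector of 0/1 of the given length, 1 exactly at label
#'   indices.
#' @export
to_binary_labels <- function(labels, length) {
  idx <- as_fs_indices(labels)
  if (!is_count(length) && length != 0) validation_error("length must be a positive count")
  if (any(idx < 1L) || any(idx > length)) {
    validation_error("label index out of range")
  }
  out <- integer(length)
  out[idx] <- 1L
  out
}

#' Map event times (seconds) to nearest sample indices of a recording
#'
#' Used to carry simulator ground truth across resampling: ground-truth
#' strike times are absolute, so after regridding they are re-expressed as
#' the nearest sample on the new grid.
#'
#' @param times event times in seconds.
#' @param rec an `imu_recording`.
#' @param source label source tag.
#' @return a `foot_strike_labels` object.
#' @export
labels_from_times <- function(times, rec, source = "ground_truth") {
  ts <- rec$timestamps
  pos <- findInterval(times, ts, all.inside = TRUE)
  # nearest of ts[pos], ts[pos+1]
  idx <- ifelse(times - ts[pos] > ts[pos + 1L] - times, pos + 1L, pos)
  idx <- sort(unique(pmin(pmax(idx, 1L), length(ts))))
  foot_strike_labels(idx, source, n_total = length(ts))
}
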