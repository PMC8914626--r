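# Per-sample 31-frame signal windows for the sequence classifier.

#' Build per-sample 31-frame windows
#'
#' Every sample of the recording becomes the anchor of exactly one window of
#' 31 frames x 12 channels: interior anchors take 15 frames either side;
#' the first 15 anchors take the 30 frames after the anchor, the last 15 the
#' 30 frames before it (so no window leaves the recording).
#'
#' @param rec an `imu_recording` (or plain N x 12 matrix with the
#'   [imu_channels()] columns).
#' @param labels binary vector of length N (1 = foot strike), or a
#'   `foot_strike_labels` object.
#' @param rate sampling rate in Hz (taken from the recording when given one).
#' @return a `window_set`: list with `windows` (array 31 x N x 12, frames x
#'   windows x channels), `labels` (integer 0/1), `center_indices`, `rate`,
#'   `participant_id`.
#' @export
build_windows <- function(rec, labels, rate = NULL) {
  if (inherits(rec, "imu_recording")) {
    x <- rec$channels
    if (is.null(rate)) rate <- 1 / mean(diff(rec$timestamps))
    pid <- rec$participant_id
  } else {
    x <- as.matrix(rec)
    if (is.null(rate)) rate <- 50
    pid <- ""
  }
  n <- nrow(x)
  if (n < 31L) validation_error("recording must have at least 31 samples")
  if (inherits(labels, "foot_strike_labels")) {
    labels <- to_binary_labels(labels, n)
  }
  if (length(labels) != n) {
    validation_error("labels length must equal recording length")
  }
  half <- 15L
  centers <- seq_len(n)
  start <- centers - half
  start[centers <= half] <- centers[centers <= half]
  start[centers >= n - half + 1L] <- centers[centers >= n - half + 1L] - 2L * half
  frame_idx <- rep(start, each = 31L) + 0:30  # row-major over windows
  w <- x[frame_idx, , drop = FALSE]
  windows <- array(w, dim = c(31L, n, ncol(x)),
                   dimnames = list(NULL, NULL, colnames(x)))
  structure(list(windows = windows, labels = as.integer(labels),
                 center_indices = centers, rate = rate,
                 participant_id = pid),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("<window_set> %d windows of %d x %d (%d positive)\n",
              d[2], d[1], d[3], sum(x$labels)))
  invisible(x)
}

#' Per-sample signal reconstructed from a window set
#'
#' Returns the value of one channel at each window's anchor sample (frame 16
#' for interior windows, frame 1 / frame 31 under the edge rules), i.e. the
#' original per-sample signal. Lets post-processing run when only windows
#' were kept.
#'
#' @param ws a `window_set`.
#' @param channel channel name.
#' @return numeric vector, one value per window.
#' @export
center_signal <- function(ws, channel = "ap") {
  d <- dim(ws$windows)
  n <- d[2]
  frame <- rep(16L, n)
  half <- 15L
  frame[seq_len(half)] <- 1L            # leading-edge windows start at anchor
  frame[(n - half + 1L):n] <- 31L       # trailing-edge windows end at anchor
  ws$windows[cbind(frame, seq_len(n), match(channel, dimnames(ws$windows)[[3]]))]
}
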