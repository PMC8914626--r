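# Step-based feature set: 62 per-step features (5 temporal, 27 descriptive,
# 30 frequency-domain) over 6 channels (ML, AP, vertical linear acceleration
# and tilt, rotation, obliquity), aggregated by min/max/mean/SD into one
# 248-value participant vector.

feature_channels <- function() c("ml", "ap", "vert", "tilt", "rotation", "obliquity")

#' Fixed, ordered registry of the 62 step-feature names
#'
#' Order: 5 temporal; descriptive blocks (min, max over accelerations, mean
#' over all 6 channels, range over orientations, SD and RMS over all 6);
#' frequency blocks per channel (spectral quartile, max magnitude, SD of
#' magnitudes, peak distinction, even/odd harmonic ratio).
#'
#' @return character vector of 62 names.
#' @export
feature_registry <- function() {
  ch <- feature_channels()
  acc <- ch[1:3]; ori <- ch[4:6]
  c("cadence", "step_time_right", "step_time_left", "stride_time",
    "symmetry_index",
    paste0("min_", acc), paste0("max_", acc), paste0("mean_", ch),
    paste0("range_", ori), paste0("sd_", ch), paste0("rms_", ch),
    paste0("quartile_fft_", ch), paste0("max_fft_", ch),
    paste0("sd_fft_", ch), paste0("peak_distinction_fft_", ch),
    paste0("reoh_", ch))
}

#' Names of the 248 aggregated participant features
#' @return character vector, feature-major / statistic-minor order.
#' @export
participant_feature_names <- function() {
  as.vector(t(outer(feature_registry(), c("min", "max", "mean", "sd"),
                    paste, sep = "_")))
}

#' Segment a recording into steps between consecutive foot strikes
#'
#' One segment per consecutive strike pair, half-open `[strike_i,
#' strike_{i+1})`, carrying the 6 feature channels plus foot and duration.
#'
#' @param rec an `imu_recording`.
#' @param fs `foot_strike_labels` or indices (>= 3 strikes).
#' @param first_foot passed to foot assignment (default infers from ML sign).
#' @return list of `step_segment`s: `channels` (matrix n x 6), `foot`,
#'   `duration` (s), `start_index`.
#' @export
segment_steps <- function(rec, fs, first_foot = "auto") {
  idx <- as_fs_indices(fs)
  if (length(idx) < 3L) validation_error("need at least 3 foot strikes to segment steps")
  rate <- 1 / mean(diff(rec$timestamps))
  feet <- assign_feet(length(idx), first_foot, channel(rec, "ml")[idx])
  x <- rec$channels[, feature_channels(), drop = FALSE]
  lapply(seq_len(length(idx) - 1L), function(i) {
    rows <- idx[i]:(idx[i + 1L] - 1L)
    structure(list(channels = x[rows, , drop = FALSE],
                   foot = feet[i + 1L],   # foot striking at the segment's end
                   duration = (idx[i + 1L] - idx[i]) / rate,
                   start_index = idx[i]),
              class = "step_segment")
  })
}

#' Symmetry index of right and left step times
#'
#' `|right - left| / (0.5 (right + left)) * 100`, in percent; 0 for perfect
#' symmetry, invariant under swapping sides.
#'
#' @param mean_right,mean_left positive mean step times (s).
#' @return percentage.
#' @export
symmetry_index <- function(mean_right, mean_left) {
  if (!is_pos(mean_right) || !is_pos(mean_left)) {
    validation_error("step times must be positive")
  }
  abs(mean_right - mean_left) / (0.5 * (mean_right + mean_left)) * 100
}

# magnitude spectrum of a detrended segment (DC excluded). Mean removal is
# the default: fitting a least-squares line to a short oscillatory segment
# injects sawtooth leakage that contaminates the even/odd harmonic ratio.
segment_spectrum <- function(x, rate, detrend = c("mean", "linear")) {
  detrend <- match.arg(detrend)
  n <- length(x)
  if (n < 4L) return(NULL)
  xd <- if (detrend == "mean") {
    x - mean(x)
  } else {
    stats::lm.fit(cbind(1, seq_len(n)), x)$residuals
  }
  kmax <- floor(n / 2)
  mag <- Mod(stats::fft(xd))[2:(kmax + 1L)]
  list(freq = (1:kmax) * rate / n, mag = mag)
}

spectral_features <- function(sp, stride_time, quartile = 0.5) {
  out <- c(quartile_fft = NA_real_, max_fft = NA_real_, sd_fft = NA_real_,
           peak_distinction_fft = NA_real_, reoh = NA_real_)
  if (is.null(sp)) return(out)
  pw <- sp$mag^2
  tot <- sum(pw)
  if (tot > 0) {
    out["quartile_fft"] <- sp$freq[which(cumsum(pw) >= quartile * tot)[1]]
    out["max_fft"] <- max(sp$mag)
    out["sd_fft"] <- stats::sd(sp$mag)
    out["peak_distinction_fft"] <- max(sp$mag) / mean(sp$mag)
  }
  if (is.finite(stride_time) && stride_time > 0) {
    f0 <- 1 / stride_time
    harm <- (1:10) * f0
    harm <- harm[harm <= sp$freq[length(sp$freq)] + (sp$freq[1] / 2)]
    if (length(harm) >= 2L) {
      bins <- vapply(harm, function(f) which.min(abs(sp$freq - f)), 0L)
      hnum <- seq_along(harm)
      even <- sum(sp$mag[bins[hnum %% 2 == 0]])
      odd <- sum(sp$mag[bins[hnum %% 2 == 1]])
      if (odd > 0) out["reoh"] <- even / odd
    }
  }
  out
}

#' Compute the 62-column step-feature table
#'
#' Per step: temporal features (cadence as 60/step duration; the most recent
#' right and left step times; stride time as their sum; symmetry index),
#' descriptive statistics of the 6 channels, and frequency-domain features
#' of each channel's linearly detrended magnitude spectrum (spectral
#' quartile: frequency below which `quartile` of spectral power lies;
#' maximum and SD of magnitudes; peak distinction: max/mean magnitude;
#' REOH: even/odd harmonic magnitude ratio anchored at the step's stride
#' frequency, harmonics 1-10 by nearest bin). Degenerate segments (< 4
#' samples) get `NA` spectral features rather than zeros; temporal features
#' needing an unseen foot are `NA` for the earliest steps.
#'
#' @param segments list of `step_segment`s from [segment_steps()].
#' @param rate sampling rate, Hz.
#' @param quartile spectral power fraction for the quartile feature (0.5 =
#'   median frequency; 0.25/0.75 available).
#' @param detrend `"mean"` (default; preserves harmonic structure) or
#'   `"linear"` (least-squares line removal) applied before the FFT.
#' @return a `step_feature_table`: data.frame with exactly the 62
#'   [feature_registry()] columns, one row per step.
#' @export
compute_step_features <- function(segments, rate, quartile = 0.5,
                                  detrend = "mean") {
  if (!length(segments)) validation_error("segments must be non-empty")
  ch <- feature_channels()
  reg <- feature_registry()
  last <- list(right = NA_real_, left = NA_real_)
  rows <- vector("list", length(segments))
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    dur <- seg$duration
    last[[seg$foot]] <- dur
    str_t <- last$right + last$left
    sym <- if (is.finite(str_t)) symmetry_index(last$right, last$left) else NA_real_
    v <- c(cadence = 60 / dur,
           step_time_right = last$right, step_time_left = last$left,
           stride_time = str_t, symmetry_index = sym)
    x <- seg$channels
    mins <- apply(x[, 1:3, drop = FALSE], 2, min)
    maxs <- apply(x[, 1:3, drop = FALSE], 2, max)
    means <- colMeans(x)
    rngs <- apply(x[, 4:6, drop = FALSE], 2, function(c_) diff(range(c_)))
    sds <- apply(x, 2, stats::sd)
    rmss <- sqrt(colMeans(x^2))
    v <- c(v, stats::setNames(mins, paste0("min_", ch[1:3])),
           stats::setNames(maxs, paste0("max_", ch[1:3])),
           stats::setNames(means, paste0("mean_", ch)),
           stats::setNames(rngs, paste0("range_", ch[4:6])),
           stats::setNames(sds, paste0("sd_", ch)),
           stats::setNames(rmss, paste0("rms_", ch)))
    spec <- lapply(seq_along(ch), function(c_) {
      spectral_features(segment_spectrum(x[, c_], rate, detrend), str_t,
                        quartile)
    })
    for (feat in c("quartile_fft", "max_fft", "sd_fft",
                   "peak_distinction_fft")) {
      v <- c(v, stats::setNames(
        vapply(spec, `[[`, 0, feat), paste0(feat, "_", ch)))
    }
    v <- c(v, stats::setNames(vapply(spec, `[[`, 0, "reoh"),
                              paste0("reoh_", ch)))
    rows[[i]] <- v[reg]
  }
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- reg
  class(tab) <- c("step_feature_table", "data.frame")
  tab
}

#' Aggregate a step-feature table into one 248-value participant vector
#'
#' Minimum, maximum, mean and SD of each of the 62 columns over all steps
#' with a defined value in that column (feature-major, statistic-minor
#' order). A column with fewer than 2 defined steps gets an `NA` SD.
#'
#' @param table a `step_feature_table`.
#' @return named numeric vector of length 248.
#' @export
aggregate_features <- function(table) {
  if (nrow(table) < 2L) validation_error("need at least 2 steps to aggregate")
  out <- unlist(lapply(feature_registry(), function(col) {
    v <- table[[col]]
    v <- v[is.finite(v)]
    if (!length(v)) {
      c(NA_real_, NA_real_, NA_real_, NA_real_)
    } else {
      c(min(v), max(v), mean(v), if (length(v) >= 2L) stats::sd(v) else NA_real_)
    }
  }))
  stats::setNames(out, participant_feature_names())
}
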