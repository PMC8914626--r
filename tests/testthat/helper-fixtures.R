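# Shared fixtures and independent oracles for the test suite.

# recording whose AP channel is a pure sinusoid (other channels zero)
make_sinusoid_recording <- function(freq, duration = 20, rate = 50, amp = 1,
                                    channel = "ap") {
  t <- seq(0, duration, by = 1 / rate)
  ch <- matrix(0, length(t), 12, dimnames = list(NULL, imu_channels()))
  ch[, channel] <- amp * sin(2 * pi * freq * t)
  imu_recording(t, ch, "sine", rate)
}

# amplitude of a sinusoid at known frequency by harmonic regression
# (insensitive to the crest falling between samples)
fitted_amplitude <- function(y, t, freq) {
  co <- stats::coef(stats::lm(y ~ sin(2 * pi * freq * t) + cos(2 * pi * freq * t)))
  sqrt(co[2]^2 + co[3]^2)
}

# irregularly sampled recording whose channels are linear ramps of time
make_ramp_recording <- function(n = 200, seed = 1) {
  set.seed(seed)
  t <- cumsum(runif(n, 0.01, 0.03))
  ch <- sapply(seq_len(12), function(k) 0.5 * k * t - k)
  colnames(ch) <- imu_channels()
  imu_recording(t, ch, "ramp", 50)
}

# toy linearly separable window set: positive windows all-ones,
# negative windows all-zeros
make_toy_window_set <- function(n = 200) {
  labs <- rep(c(0L, 1L), length.out = n)
  X <- array(0, dim = c(31, n, 12),
             dimnames = list(NULL, NULL, imu_channels()))
  X[, labs == 1L, ] <- 1
  structure(list(windows = X, labels = labs, center_indices = seq_len(n),
                 rate = 50, participant_id = "toy"),
            class = "window_set")
}

# exhaustive maximum one-to-one matching oracle (all injective assignments,
# feasible for <= 8 events per side)
oracle_max_matching <- function(truth, pred, tol) {
  best <- 0L
  recurse <- function(i, used) {
    if (i > length(truth)) {
      best <<- max(best, sum(used))
      return(invisible())
    }
    # upper-bound prune
    if (sum(used) + (length(truth) - i + 1L) <= best) return(invisible())
    for (j in seq_along(pred)) {
      if (!used[j] && abs(truth[i] - pred[j]) <= tol) {
        used[j] <- TRUE
        recurse(i + 1L, used)
        used[j] <- FALSE
      }
    }
    recurse(i + 1L, used)  # leave truth i unmatched
  }
  recurse(1L, logical(length(pred)))
  best
}

# standard preprocessed synthetic trial + truth on the processed grid
prep_trial <- function(config) {
  tr <- simulate_trial(config)
  rec <- lowpass_zero_lag(resample_uniform(tr$recording, 50))
  list(trial = tr, rec = rec,
       truth = labels_from_times(tr$true_fs_times, rec))
}
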