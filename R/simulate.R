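# Synthetic gait simulator: 12-channel pelvis-IMU walking recordings with
# exact foot-strike ground truth. Each strike injects a Gaussian
# anterior-posterior acceleration pulse followed after a short lag by a
# vertical pulse -- the morphology the labelling rule and the detector
# exploit -- plus medio-lateral sway, orientation oscillation at stride
# frequency, sensor noise, timestamp jitter, and optional artifacts.

#' Configuration of the gait simulator
#'
#' Defaults emulate a two-minute walk test of a slow walker recorded by a
#' pelvis-mounted phone at a nominally 50 Hz, variably spaced rate.
#'
#' @param duration trial length in seconds.
#' @param nominal_rate nominal sampling rate, Hz.
#' @param mean_cadence mean cadence, steps/min.
#' @param step_time_cv coefficient of variation of step times (unitless).
#' @param asymmetry_ratio ratio of right to left mean step time.
#' @param ap_peak_amp,vert_peak_amp pulse amplitudes, m/s^2.
#' @param pulse_width Gaussian pulse full width at half maximum, s.
#' @param vert_lag delay of the vertical pulse after the AP pulse, s.
#' @param noise_sd white acceleration noise, m/s^2.
#' @param timestamp_jitter_sd jitter of sample spacing, s.
#' @param dropout_prob probability that a step's AP pulse is attenuated (to
#'   15% of its amplitude), emulating a poorly expressed strike.
#' @param spurious_peak_rate rate of extra AP pulses, peaks/min.
#' @param seed integer seed; the whole trial is a deterministic function of
#'   the config.
#' @return a `gait_sim_config` object.
#' @export
gait_sim_config <- function(duration = 120, nominal_rate = 50,
                            mean_cadence = 105, step_time_cv = 0.04,
                            asymmetry_ratio = 1.05,
                            ap_peak_amp = 3, vert_peak_amp = 2.5,
                            pulse_width = 0.08, vert_lag = 0.12,
                            noise_sd = 0.3, timestamp_jitter_sd = 0.002,
                            dropout_prob = 0, spurious_peak_rate = 0,
                            seed = 1) {
  cfg <- list(duration = duration, nominal_rate = nominal_rate,
              mean_cadence = mean_cadence, step_time_cv = step_time_cv,
              asymmetry_ratio = asymmetry_ratio, ap_peak_amp = ap_peak_amp,
              vert_peak_amp = vert_peak_amp, pulse_width = pulse_width,
              vert_lag = vert_lag, noise_sd = noise_sd,
              timestamp_jitter_sd = timestamp_jitter_sd,
              dropout_prob = dropout_prob,
              spurious_peak_rate = spurious_peak_rate,
              seed = as.integer(seed))
  for (f in c("duration", "nominal_rate", "mean_cadence", "asymmetry_ratio",
              "ap_peak_amp", "vert_peak_amp", "pulse_width", "vert_lag")) {
    if (!is_pos(cfg[[f]])) validation_error(sprintf("%s must be positive", f))
  }
  for (f in c("step_time_cv", "noise_sd", "timestamp_jitter_sd",
              "spurious_peak_rate")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) {
      validation_error(sprintf("%s must be non-negative", f))
    }
  }
  if (!is_prob(cfg$dropout_prob)) validation_error("dropout_prob must be in [0, 1]")
  structure(cfg, class = "gait_sim_config")
}

# sum of Gaussian pulses evaluated on t; only a +-5 sd neighbourhood of each
# centre is touched
add_pulses <- function(y, t, centers, amps, sigma) {
  for (k in seq_along(centers)) {
    c_k <- centers[k]
    i <- which(t >= c_k - 5 * sigma & t <= c_k + 5 * sigma)
    y[i] <- y[i] + amps[k] * exp(-((t[i] - c_k)^2) / (2 * sigma^2))
  }
  y
}

#' Simulate one walking trial
#'
#' Foot-strike times are drawn by alternating left/right step times
#' (lognormal around asymmetric means with the configured CV); signals are
#' synthesised around them. Deterministic given the config seed.
#'
#' @param config a [gait_sim_config()].
#' @return a `synthetic_trial`: list with `recording` (`imu_recording`),
#'   `true_fs` (`foot_strike_labels` on the recording's own grid),
#'   `true_fs_times` (strike times, s), `true_step_times` (data.frame with
#'   `time`, `foot`, `step_time`), and `config`.
#' @export
simulate_trial <- function(config) {
  if (!inherits(config, "gait_sim_config")) {
    config <- do.call(gait_sim_config, as.list(config))
  }
  cfg <- config
  with_seed(cfg$seed, {
    # --- strike schedule -----------------------------------------------------
    mean_step <- 60 / cfg$mean_cadence
    left_mean <- 2 * mean_step / (1 + cfg$asymmetry_ratio)
    right_mean <- left_mean * cfg$asymmetry_ratio
    sdlog <- sqrt(log(1 + cfg$step_time_cv^2))
    draw_step <- function(mu) {
      stats::rlnorm(1, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
    }
    t_k <- 0.4            # walk starts shortly after recording onset
    foot <- "left"        # foot striking at each event; first strike left
    times <- numeric(0); feet <- character(0); steps <- numeric(0)
    prev <- t_k
    repeat {
      st <- draw_step(if (foot == "right") right_mean else left_mean)
      t_next <- if (!length(times)) t_k else prev + st
      if (t_next > cfg$duration - 0.3) break
      times <- c(times, t_next)
      feet <- c(feet, foot)
      steps <- c(steps, if (length(times) == 1L) NA_real_ else st)
      prev <- t_next
      foot <- if (foot == "left") "right" else "left"
    }
    n_fs <- length(times)
    if (n_fs < 3L) validation_error("config yields fewer than 3 foot strikes")

    # --- timestamp grid ------------------------------------------------------
    h <- 1 / cfg$nominal_rate
    n_t <- ceiling(cfg$duration * cfg$nominal_rate * 1.2) + 10L
    dt <- pmax(h + stats::rnorm(n_t, 0, cfg$timestamp_jitter_sd), 0.25 * h)
    ts <- cumsum(c(0, dt))
    ts <- ts[ts <= cfg$duration]
    n <- length(ts)

    # --- signal synthesis ----------------------------------------------------
    sigma <- cfg$pulse_width / 2.355   # FWHM -> sd
    ap_amps <- rep(cfg$ap_peak_amp, n_fs)
    if (cfg$dropout_prob > 0) {
      drop <- stats::rbinom(n_fs, 1, cfg$dropout_prob) == 1L
      ap_amps[drop] <- 0.15 * ap_amps[drop]
    }
    ap <- add_pulses(numeric(n), ts, times, ap_amps, sigma)
    if (cfg$spurious_peak_rate > 0) {
      n_sp <- stats::rpois(1, cfg$spurious_peak_rate * cfg$duration / 60)
      if (n_sp > 0) {
        sp_t <- stats::runif(n_sp, 1, cfg$duration - 1)
        ap <- add_pulses(ap, ts, sp_t, rep(0.8 * cfg$ap_peak_amp, n_sp), sigma)
      }
    }
    vert <- add_pulses(numeric(n), ts, times + cfg$vert_lag,
                       rep(cfg$vert_peak_amp, n_fs), sigma)
    ml_sign <- ifelse(feet == "right", 1, -1)   # convention: +ML at right strikes
    ml <- add_pulses(numeric(n), ts, times, ml_sign * 0.35 * cfg$ap_peak_amp,
                     sigma * 1.4)

    f_stride <- cfg$mean_cadence / 120          # strides per second
    tilt <- 2.0 * sin(2 * pi * 2 * f_stride * ts)
    obliquity <- 3.0 * sin(2 * pi * f_stride * ts)
    rotation <- 4.0 * sin(2 * pi * f_stride * ts + pi / 3)
    gx <- 0.30 * sin(2 * pi * f_stride * ts + pi / 2)
    gy <- 0.25 * sin(2 * pi * 2 * f_stride * ts)
    gz <- 0.35 * sin(2 * pi * f_stride * ts)

    nz <- function(s) if (s > 0) stats::rnorm(n, 0, s) else numeric(n)
    ap <- ap + nz(cfg$noise_sd)
    ml <- ml + nz(cfg$noise_sd)
    vert <- vert + nz(cfg$noise_sd)
    ch <- cbind(
      ax_raw = ml + 0.1 + nz(cfg$noise_sd),
      ay_raw = vert + 9.81 + nz(cfg$noise_sd),
      az_raw = ap - 0.2 + nz(cfg$noise_sd),
      ap = ap, ml = ml, vert = vert,
      gx = gx + nz(0.1 * cfg$noise_sd), gy = gy + nz(0.1 * cfg$noise_sd),
      gz = gz + nz(0.1 * cfg$noise_sd),
      tilt = tilt + nz(0.5 * cfg$noise_sd),
      obliquity = obliquity + nz(0.5 * cfg$noise_sd),
      rotation = rotation + nz(0.5 * cfg$noise_sd))

    rec <- imu_recording(ts, ch, sprintf("sim%08d", cfg$seed), cfg$nominal_rate)
    structure(
      list(recording = rec,
           true_fs = labels_from_times(times, rec),
           true_fs_times = times,
           true_step_times = data.frame(time = times, foot = feet,
                                        step_time = steps),
           config = cfg),
      class = "synthetic_trial")
  })
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("<synthetic_trial> %d samples, %d foot strikes, seed %d\n",
              n_samples(x$recording), length(x$true_fs$indices),
              x$config$seed))
  invisible(x)
}

#' Simulate a labelled cohort for fall-risk experiments
#'
#' Fall-risk participants are drawn with elevated step-time variability and
#' left/right asymmetry relative to no-risk participants; `effect_size`
#' scales the separation (0 makes the two class-conditional distributions
#' identical). Per-participant cadence, variability and asymmetry are drawn
#' around the base config, each trial getting its own derived seed.
#'
#' @param n number of participants (>= 2; both classes must be represented).
#' @param risk_fraction fraction labelled fall-risk (default matches a
#'   roughly one-third prevalence).
#' @param effect_size multiplier on the class contrast (1 = strong contrast:
#'   fall-risk mean step-time CV about 3x the no-risk mean plus 12% extra
#'   asymmetry).
#' @param base_config `gait_sim_config` the cohort is drawn around.
#' @param label_rule optional function(config) -> logical overriding the
#'   labels after configs are drawn; must yield both classes.
#' @param seed cohort seed.
#' @return list of elements `list(trial = synthetic_trial, fall_risk = logical)`.
#' @export
make_cohort <- function(n, risk_fraction = 0.34, effect_size = 1,
                        base_config = gait_sim_config(),
                        label_rule = NULL, seed = 1) {
  if (!is_count(n) || n < 2) validation_error("n must be an integer >= 2")
  n_risk <- min(max(1L, round(n * risk_fraction)), n - 1L)
  seeds <- derive_seeds(seed, n + 1L)
  labels <- with_seed(seeds[n + 1L], sample(rep(c(TRUE, FALSE), c(n_risk, n - n_risk))))
  cohort <- vector("list", n)
  for (i in seq_len(n)) {
    p <- with_seed(seeds[i], {
      list(cad = stats::rnorm(1, base_config$mean_cadence, 5),
           cv_mult = stats::rlnorm(1, 0, 0.15),
           extra_asym = abs(stats::rnorm(1, 0, 0.02)),
           u = stats::runif(1))
    })
    risk <- labels[i]
    cv <- base_config$step_time_cv * p$cv_mult *
      (1 + (if (risk) 2 * effect_size else 0))
    asym <- base_config$asymmetry_ratio + p$extra_asym +
      (if (risk) 0.12 * effect_size * (0.5 + p$u) else 0)
    cfg <- gait_sim_config(
      duration = base_config$duration, nominal_rate = base_config$nominal_rate,
      mean_cadence = max(p$cad, 60), step_time_cv = cv,
      asymmetry_ratio = asym, ap_peak_amp = base_config$ap_peak_amp,
      vert_peak_amp = base_config$vert_peak_amp,
      pulse_width = base_config$pulse_width, vert_lag = base_config$vert_lag,
      noise_sd = base_config$noise_sd,
      timestamp_jitter_sd = base_config$timestamp_jitter_sd,
      dropout_prob = base_config$dropout_prob,
      spurious_peak_rate = base_config$spurious_peak_rate,
      seed = seeds[i])
    if (!is.null(label_rule)) labels[i] <- isTRUE(label_rule(cfg))
    trial <- simulate_trial(cfg)
    trial$recording$participant_id <- sprintf("P%03d", i)
    cohort[[i]] <- list(trial = trial, fall_risk = labels[i])
  }
  lab <- vapply(cohort, `[[`, logical(1), "fall_risk")
  if (length(unique(lab)) < 2L) {
    validation_error("cohort labels are degenerate: only one class present")
  }
  cohort
}
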