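# End-to-end pipeline: simulate -> preprocess -> label -> detect ->
# postprocess -> stride metrics -> step features -> fall risk, as one
# reproducible, seeded run.

#' Pipeline configuration
#'
#' Bundles every stage's parameters. The preprocessing defaults mirror the
#' walk-test protocol: resample at 50 Hz, fourth-order zero-lag low-pass at
#' 4 Hz, evaluate on the first `validation_duration` seconds.
#'
#' @param n_participants cohort size.
#' @param sim base [gait_sim_config()] the cohort is drawn around.
#' @param risk_fraction,effect_size cohort composition, see [make_cohort()].
#' @param rate resampling rate, Hz.
#' @param cutoff,filter_order low-pass filter settings.
#' @param validation_duration seconds of each trial used for evaluation (the
#'   walk test's first two minutes; shorter for short synthetic trials).
#' @param labeling [labeling_params()] for the ground-truth heuristic.
#' @param fs_model [fs_model_config()] for the sequence detector.
#' @param pp [postprocess_params()].
#' @param mdc [mdc_thresholds()].
#' @param rf [rf_config()].
#' @param train_fraction fraction of participants used to train the
#'   detector; the rest are held out for foot-strike evaluation.
#' @param tolerance matching tolerance, frames.
#' @param seed global seed; every stochastic stage derives its seed from it.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(n_participants = 10,
                            sim = gait_sim_config(duration = 60),
                            risk_fraction = 0.34, effect_size = 1,
                            rate = 50, cutoff = 4, filter_order = 4,
                            validation_duration = 30,
                            labeling = labeling_params(),
                            fs_model = fs_model_config(epochs = 4),
                            pp = postprocess_params(),
                            mdc = mdc_thresholds(),
                            rf = rf_config(),
                            train_fraction = 0.75,
                            tolerance = 2, seed = 1) {
  structure(list(n_participants = n_participants, sim = sim,
                 risk_fraction = risk_fraction, effect_size = effect_size,
                 rate = rate, cutoff = cutoff, filter_order = filter_order,
                 validation_duration = validation_duration,
                 labeling = labeling, fs_model = fs_model, pp = pp,
                 mdc = mdc, rf = rf, train_fraction = train_fraction,
                 tolerance = tolerance, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_fingerprint <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(config, file = f)
  unname(tools::md5sum(f))
}

#' Run the full walk-test analysis pipeline on a synthetic cohort
#'
#' Stages: simulate a labelled cohort; preprocess every trial (resample,
#' zero-lag low-pass, truncate to the validation span); heuristic
#' ground-truth labelling (the "manual" route); train the sequence detector
#' on a participant-level training split -- on the full trial span in
#' `"six_minute"` mode, on the validation span only in `"two_minute"` mode --
#' and evaluate post-processed predictions on the held-out participants with
#' tolerance matching; compare manual vs automated stride parameters against
#' MDC; compute 248-entry participant vectors from manual foot strikes for
#' everyone and run cross-validated fall-risk classification.
#'
#' @param config a [pipeline_config()].
#' @param mode `"six_minute"` (train on full trials) or `"two_minute"`
#'   (train on the validation span only).
#' @return a run report list: `fs` (pooled confusion + metrics + per-trial
#'   counters), `stride` (per-trial MDC comparison tables and mean
#'   differences), `fall_risk` (confusion + metrics), `mode`, `seed`,
#'   `config_fingerprint`, `n_participants`, `train_ids`, `test_ids`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         mode = c("six_minute", "two_minute")) {
  mode <- match.arg(mode)
  seeds <- derive_seeds(config$seed, 4L)
  cohort <- make_cohort(config$n_participants,
                        risk_fraction = config$risk_fraction,
                        effect_size = config$effect_size,
                        base_config = config$sim, seed = seeds[1])

  prep <- lapply(cohort, function(el) {
    rec <- resample_uniform(el$trial$recording, config$rate)
    rec <- lowpass_zero_lag(rec, config$cutoff, config$filter_order)
    val <- truncate_recording(rec, config$validation_duration)
    manual <- label_foot_strikes(val, config$labeling)
    list(full = rec, val = val, manual = manual,
         truth = labels_from_times(el$trial$true_fs_times, val),
         fall_risk = el$fall_risk)
  })

  n <- length(prep)
  n_train <- max(1L, min(n - 1L, round(config$train_fraction * n)))
  ord <- with_seed(seeds[2], sample.int(n))
  train_ids <- sort(ord[seq_len(n_train)])
  test_ids <- sort(ord[(n_train + 1L):n])

  train_sets <- lapply(train_ids, function(i) {
    rec <- if (mode == "six_minute") prep[[i]]$full else prep[[i]]$val
    truth <- labels_from_times(cohort[[i]]$trial$true_fs_times, rec)
    build_windows(rec, truth)
  })
  fs_cfg <- config$fs_model
  fs_cfg$seed <- seeds[3]
  model <- train_fs_model(train_sets, fs_cfg)

  counters <- list()
  cms <- list()
  stride_rows <- list()
  for (i in test_ids) {
    p <- prep[[i]]
    ws <- build_windows(p$val, p$truth)
    raw_pred <- predict_fs(model, ws)
    pred <- postprocess_predictions(raw_pred, channel(p$val, "ap"),
                                    config$rate, config$pp)
    cms[[length(cms) + 1L]] <- match_with_tolerance(
      p$truth, pred, config$tolerance, total = n_samples(p$val))
    counters[[length(counters) + 1L]] <- list(
      participant = p$val$participant_id,
      raw_predictions = length(raw_pred$indices),
      final_predictions = length(pred$indices),
      removed_by_consolidation = length(raw_pred$indices) -
        length(consolidate_runs(raw_pred, channel(p$val, "ap"))$indices),
      inserted = length(pred$indices) -
        length(consolidate_runs(raw_pred, channel(p$val, "ap"))$indices),
      true_strikes = length(p$truth$indices))
    if (length(pred$indices) >= 3L && length(p$manual$indices) >= 3L) {
      man_sp <- compute_stride_parameters(p$manual, config$rate,
                                          ml_signal = channel(p$val, "ml"))
      aut_sp <- compute_stride_parameters(pred, config$rate,
                                          ml_signal = channel(p$val, "ml"))
      cmp <- compare_to_mdc(man_sp, aut_sp, config$mdc)
      cmp$participant <- p$val$participant_id
      stride_rows[[length(stride_rows) + 1L]] <- cmp
    }
  }
  pooled <- pool_confusion(cms)
  stride_tab <- if (length(stride_rows)) do.call(rbind, stride_rows)

  feats <- t(vapply(prep, function(p) {
    segs <- segment_steps(p$val, p$manual)
    aggregate_features(compute_step_features(segs, config$rate))
  }, numeric(248)))
  labels <- vapply(prep, `[[`, logical(1), "fall_risk")
  rf_cfg <- config$rf
  rf_cfg$seed <- seeds[4]
  fr <- evaluate_fall_risk(fall_risk_dataset(feats, labels, "manual_fs"),
                           rf_cfg)

  list(mode = mode, seed = config$seed,
       n_participants = config$n_participants,
       train_ids = train_ids, test_ids = test_ids,
       fs = list(confusion = pooled, metrics = compute_metrics(pooled),
                 counters = counters, training_loss = model$history),
       stride = list(per_trial = stride_tab,
                     mean_differences = if (!is.null(stride_tab)) {
                       tapply(stride_tab$difference, stride_tab$parameter, mean)
                     }),
       fall_risk = list(confusion = fr$confusion, metrics = fr$metrics),
       config_fingerprint = config_fingerprint(config))
}
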