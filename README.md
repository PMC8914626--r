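# stridetect

Gait analysis for smartphone walk tests: automated foot-strike detection
from pelvis-mounted IMU signals, stride parameters, step-based features,
and fall-risk classification.

A phone strapped to the posterior pelvis during a two- or six-minute walk
test records 12 signal channels at a nominally 50 Hz, variably spaced rate:
raw and linear acceleration (m/s²), angular velocity (rad/s), and pelvis
orientation (tilt, obliquity, rotation; degrees). `stridetect` turns such a
recording into clinical gait outcomes:

1. **Preprocessing** — linear re-interpolation onto a uniform 50 Hz grid,
   fourth-order zero-lag Butterworth low-pass at 4 Hz, truncation to the
   analysis span (120 s at 50 Hz → 6000 samples).
2. **Foot-strike (FS) detection** — two routes:
   a deterministic labelling heuristic (an anterior–posterior acceleration
   peak followed within 0.25 s by a vertical acceleration peak), and an
   LSTM sequence classifier over per-sample 31-frame × 12-channel windows
   (100 LSTM units, 50-unit dense layer, batch 64, dropout 0.4),
   implemented from scratch with BPTT and verified against
   finite-difference gradients.
3. **Rule-based error correction** — runs of consecutive predictions
   collapse to the AP-acceleration peak; inter-strike gaps longer than
   1.5× the previous step duration receive an inserted strike at the AP
   argmax inside an adaptive locking window.
4. **Evaluation** — maximum one-to-one event matching within ±2 frames
   (±0.04 s), confusion matrices, and accuracy/sensitivity/specificity/
   precision with half-up rounding.
5. **Stride parameters** — step time, stride time (between same-foot
   strikes), cadence `(n−1)/elapsed × 60`, compared against minimal
   detectable change (MDC) thresholds (0.042 s / 0.772 s / 8.44 steps/min).
6. **Step features** — 62 per-step features (5 temporal, 27 descriptive,
   30 frequency-domain, including the even/odd harmonic ratio REOH and the
   symmetry index `|R−L|/(0.5(R+L))×100`), aggregated by min/max/mean/SD
   into one 248-entry participant vector.
7. **Fall-risk classification** — a seeded random forest over the 248
   features with stratified participant-level cross-validation.

Because clinical walk-test recordings are private, the package bundles a
synthetic gait simulator (`simulate_trial()`, `make_cohort()`) that
produces 12-channel recordings with exact foot-strike ground truth,
configurable cadence, left/right asymmetry, step-time variability, noise,
and artifacts. Every stage of the pipeline is tested against it.

## Worked example

```r
library(stridetect)

# simulate a 2-minute walk at 105 steps/min and preprocess it
trial <- simulate_trial(gait_sim_config(duration = 120, mean_cadence = 105,
                                        seed = 7))
rec <- lowpass_zero_lag(resample_uniform(trial$recording, 50), cutoff = 4)

# heuristic foot-strike labelling and comparison with ground truth
fs <- label_foot_strikes(rec)
truth <- labels_from_times(trial$true_fs_times, rec)
cm <- match_with_tolerance(truth, fs, tolerance = 2, total = n_samples(rec))
compute_metrics(cm)
#> accuracy 100  sensitivity 100  specificity 100  precision 100

# stride parameters
compute_stride_parameters(fs, 50, ml_signal = channel(rec, "ml"))
#> <stride_parameters> 208 strikes: step 0.575 (0.028) s, stride 1.149 (0.034) s, cadence 104.4 steps/min

# 248-entry participant feature vector
vec <- aggregate_features(compute_step_features(segment_steps(rec, fs), 50))
length(vec)
#> [1] 248
round(vec[c("symmetry_index_mean", "reoh_ap_mean", "sd_ap_sd")], 3)
#> symmetry_index_mean        reoh_ap_mean            sd_ap_sd
#>               6.199               0.821               0.042
```

The detection metrics read: every one of the 208 true strikes was matched
within ±2 frames and no spurious strike remained, even at the simulator's
default noise level. The recovered cadence (104.4 steps/min) matches the
configured 105 up to the trial's sampled step-time variation; the mean
symmetry index of ~6% reflects the configured 1.05 right/left asymmetry
plus step-time noise.

Training the sequence detector and classifying fall risk on a cohort:

```r
cohort <- make_cohort(20, effect_size = 1,
                      base_config = gait_sim_config(duration = 60), seed = 1)
report <- run_pipeline(pipeline_config(n_participants = 10, seed = 1),
                       mode = "six_minute")
report$fs$metrics       # held-out, post-processed detection metrics
report$fall_risk$metrics
```

A thin command-line front end ships in `inst/cli/walktest.R`
(`simulate`, `preprocess`, `label`, `postprocess`, `metrics`, `features`,
`run-all`).

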