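---
title: "Methods: smartphone walk-test gait analysis with stridetect"
author: "stridetect authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smartphone walk-test gait analysis with stridetect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Two- and six-minute walk tests (2MWT/6MWT) are standard over-ground mobility
assessments. A smartphone strapped to the posterior pelvis records
acceleration, angular velocity and orientation at a nominally 50 Hz but
variably spaced rate. From these signals the pipeline must (i) find every
foot strike — the initial ground contact that delimits gait cycles — (ii)
derive stride parameters (step time, stride time, cadence), (iii) condense
each walk into a fixed-length feature vector, and (iv) classify whether the
walker is at fall risk (defined as at least one self-reported fall in the
prior six months). Populations with atypical gait, such as lower-limb
prosthesis users, defeat simple rule-based step detectors, which motivates
the sequence-model detector plus rule-based error correction implemented
here.

`stridetect` implements the full chain, together with a synthetic gait
simulator that provides exact ground truth, so every stage can be exercised
and quantified without access to clinical recordings.

## Data model and preprocessing

A recording (`imu_recording`) holds 12 channels against strictly increasing
timestamps: raw acceleration XYZ (device frame), linear acceleration mapped
to body axes (anterior–posterior AP, medio-lateral ML, vertical), angular
velocity XYZ, and pelvis orientation (tilt, obliquity, rotation, degrees).
Device-to-body mapping is never implied by hardware alone, so it is an
explicit, validated bijection (`axis_convention()`); the default assumes a
portrait phone, screen facing backwards (x → ML, y → vertical, z → AP). All
downstream code consumes body axes only.

Preprocessing follows the walk-test protocol:

* `resample_uniform()` — linear interpolation onto a uniform grid at 50 Hz.
  Linear interpolation is monotone, shape-preserving, and exact on locally
  linear signals, which is all that ~20 ms gaps require. The grid is
  anchored at the **first timestamp** (not zero), so absolute event times
  survive regridding; the last grid point is the largest not after the last
  input timestamp (within 1e-9 s). Under this convention a span of exactly
  `k/rate` seconds yields `k + 1` samples; a six-minute trial spanning
  360.98 s yields 18,050 grid points, and truncation (strictly-before cut)
  to 360.98 s leaves 18,049. Endpoint conventions differ between tools;
  ours is stated here precisely because printed sample counts depend on it.
* `lowpass_zero_lag()` — fourth-order zero-lag Butterworth, 4 Hz cut-off.
  The default implementation applies the exact forward–backward analog
  Butterworth magnitude `1/(1 + (f/f_c)^8)` as a real gain in the frequency
  domain on an even (mirrored) extension of each channel: zero phase by
  construction, DC gain exactly 1, and stop-band behaviour that matches the
  closed form at every frequency. The classic IIR route
  (`method = "filtfilt"`) is also provided; note that a bilinear-transform
  IIR over-attenuates well above the cut-off (frequency warping compresses
  the response toward Nyquist — at 10 Hz on a 50 Hz grid by roughly a
  factor of three), which is why the frequency-sampled form is the default
  for a filter whose stop-band contract is stated analytically. The
  `filtfilt` path reflect-pads and centres each channel first, since
  zero-state filtering otherwise leaves visible transients at the edges of
  signals with non-zero baselines (e.g. vertical acceleration around
  gravity).
* `truncate_recording()` — keeps samples strictly before
  `first timestamp + duration`; 120 s at 50 Hz keeps exactly 6000 samples.

## Ground-truth labelling heuristic

Human raters label a foot strike where an AP acceleration peak is followed
shortly by a vertical acceleration peak, resolving ambiguous cases by
consensus and video. `label_foot_strikes()` is the deterministic analogue:
AP local maxima with prominence ≥ `ap_prominence_min` (default 0.8 m/s²)
that have a vertical local maximum with prominence ≥ `vert_prominence_min`
(0.4 m/s²) within `(0, max_vert_lag]` (0.25 s — inside a typical
loading-response interval and below any plausible step time), with
candidates closer than `min_step_separation` (0.3 s) resolved in favour of
the larger AP peak. Prominence (height above the higher of the two saddles
separating a peak from higher terrain) rather than raw height makes the
rule robust to slow baseline drift. The thresholds have no published
values; they are calibrated once against the simulator and stated here. The
heuristic stands in for the human-in-the-loop step everywhere the pipeline
needs "manual" labels.

## The synthetic gait simulator

`simulate_trial()` synthesises the signal morphology the labelling rule and
the detector exploit, with exact ground truth:

* Foot-strike times: alternating left/right step times drawn lognormally
  around asymmetric means (`asymmetry_ratio` = right/left mean step time)
  with coefficient of variation `step_time_cv`; the overall mean step time
  is `60/mean_cadence`.
* Each strike injects a Gaussian AP pulse (FWHM `pulse_width` = 0.08 s,
  amplitude 3 m/s²) followed after `vert_lag` = 0.12 s by a vertical pulse
  (2.5 m/s²); ML gets alternating-sign sway pulses (+ at right strikes, the
  convention the automatic foot assignment relies on); orientation channels
  oscillate at stride frequency (tilt at step frequency); raw acceleration
  adds gravity in the device frame; white noise (`noise_sd` = 0.3 m/s²),
  timestamp jitter (2 ms), optional AP-pulse dropout and spurious AP peaks
  complete the signal.
* Defaults describe a two-minute trial of a slow walker (cadence 105
  steps/min, CV 4%, asymmetry 1.05) — values in the range reported for
  lower-limb prosthesis users — and are fixed once here, not tuned per
  experiment.

`make_cohort()` draws labelled cohorts: fall-risk participants receive
elevated step-time CV (mean ×(1 + 2·effect_size)) and extra asymmetry
(+0.12·effect_size·U(0.5, 1.5)); at `effect_size = 0` the two
class-conditional distributions coincide exactly, giving a proper null.

What the simulator does **not** emulate: soft-tissue artifact, turning at
hallway ends, walking-aid signatures, non-stationary fatigue effects, or
any physically derived pelvis dynamics. Passing tests therefore demonstrate
that each stage implements its contract and that the chain recovers known
ground truth under this morphology — not clinical performance on real
amputee gait, which only the private cohort could establish.

## Windows and the sequence detector

`build_windows()` gives every sample a 31-frame × 12-channel window (15
frames ≈ 0.3 s either side of the anchor); the first and last 15 anchors
use the 30 frames after/before the anchor so no window leaves the
recording. One window per sample, exactly.

The detector is an LSTM read out at the final frame, a 50-unit ReLU dense
layer, and a sigmoid output: 100 LSTM units, batch size 64, dropout 0.4 on
the LSTM output — the published configuration. The implementation is
self-contained R (batched forward pass, backpropagation through time, Adam
at 1e-3, inverted dropout), with gradients verified against finite
differences in the test suite. Choices the published configuration leaves
open, fixed here:

* **Epochs and optimizer**: Adam, learning rate 1e-3, 8 epochs by default
  (5 in the bundled experiments — losses plateau earlier on synthetic
  signals).
* **Class imbalance**: strikes are ~3% of samples; the loss weights each
  class by `total/(2·class count)`. Training additionally subsamples
  negative windows (`negative_ratio` = 4 per positive) but always keeps
  every window within 5 frames of a strike — these near-misses are what the
  model must learn to reject, and they are exactly the windows that produce
  the consecutive-prediction runs the post-processor consolidates.
* **Normalisation**: per-channel standardisation by training-set statistics
  (orientation channels are two orders of magnitude above accelerations),
  stored on the model handle.
* **Threshold**: predictions are probability ≥ 0.5 by default, configurable.

Evaluation matches predicted to true strikes one-to-one within ±2 frames
(±0.04 s) by a two-pointer sweep — provably maximum for point matching on a
line, ties resolved toward the earlier truth index, and verified
exhaustively against a brute-force maximum-matching oracle. Every unmatched
truth is a false negative, every unmatched prediction a false positive, and
every remaining sample a true negative (this convention reproduces the
~400k negative counts of per-sample evaluation). Metrics are reported as
percentages rounded **half-up** to one decimal: accuracy 61/80 must print
as 76.3, and banker's rounding would print 76.2. A metric with a zero
denominator is undefined (`NA`), never 0. `cross_validate()` partitions at
the participant level — windows of one walker never appear on both sides of
a fold — and sums fold matrices elementwise into the pooled matrix.

## Post-processing

Two rules correct the detector's characteristic errors:

* `consolidate_runs()`: each maximal run of consecutive predicted samples
  collapses to the single sample of maximum AP acceleration in the run.
* `insert_missed_steps()`: scanning left to right, a gap between
  consecutive strikes longer than `gap_factor` (1.5) times the previous
  step duration receives one inserted strike at the AP argmax of the gap
  interior, after excluding a locking margin of `locking_margin` (0.4)
  times the previous step duration at each end. The margin makes the
  under-specified "adaptive locking period" concrete: it scales with the
  walker's own step time (adaptive), it is refractory (insertions cannot
  crowd existing strikes), and it guarantees no inserted step time below
  0.4× the previous step. The scan repeats up to `max_passes` (6) times so
  a gap hiding several missed steps fills incrementally. The previous-step
  duration for the first gap — undefined by construction — uses the trial's
  median step duration. Whether a real locking period should scale with
  cadence or stay fixed is unknowable from the published description; the
  margin is configurable, and a fixed-width variant amounts to setting
  `gap_factor` and the margin against a constant.

The full chain is idempotent on simulator fixtures (verified in tests), and
insertion never removes an existing prediction.

## Stride parameters

Step time is the interval between consecutive strikes, attributed to the
striking foot; stride time the interval between same-foot strikes (always
the sum of its two constituent step times); cadence `(n−1)/elapsed × 60`,
which is unbiased on partial windows and matches the uniform-gait closed
form (21 strikes in 10 s → 120 steps/min). A pelvis sensor cannot observe
feet directly: the default `first_foot = "auto"` assigns the first strike
by correlating the ML acceleration sign at strikes with the alternating
pattern (+ML at right strikes under the default convention) — **this is a
convention, prominently overridable**, and all per-foot outputs depend on
it. Differences between manual- and automated-strike parameters are
compared against minimal-detectable-change thresholds for healthy older
adults (step time 0.042 s, stride time 0.772 s, cadence 8.44 steps/min) —
used, as in the source protocol, because no amputee-specific MDC exists.

## Step features

Steps are the half-open spans `[strike_i, strike_{i+1})`. Per step, 62
features over six channels (ML, AP, vertical linear acceleration; tilt,
rotation, obliquity):

* 5 temporal: cadence (60/step duration), most recent right and left step
  times, stride time (their sum), symmetry index
  `|R−L|/(0.5(R+L))×100`. Steps before both feet have been seen carry `NA`
  for the unseen side, flagged rather than zeroed.
* 27 descriptive: min/max of the accelerations, mean/SD/RMS of all six
  channels, range of the orientations.
* 30 spectral, on the mean-removed, unwindowed DFT of each channel
  (magnitudes, DC excluded): spectral quartile (lowest frequency
  accumulating 50% of power; 25%/75% via `quartile`), maximum magnitude, SD
  of magnitudes, peak distinction (max/mean magnitude — a dimensionless
  peak-salience measure), and REOH, the even/odd ratio of magnitudes at
  harmonics 1–10 of the step's stride frequency (1/stride time), nearest
  bin, harmonics above Nyquist dropped. "Spectral quartile" and "peak
  distinction" have no published definitions; these are this package's
  documented choices, with median frequency being the standard
  gait-literature reading of a single spectral location parameter. Mean
  removal rather than least-squares line removal is deliberate: fitting a
  line to a short oscillatory segment injects sawtooth leakage across all
  bins, which contaminates the even/odd harmonic ratio; a `detrend =
  "linear"` option exists. Windowing is off by default (tapers are
  destructive on 20–30-sample segments); a Hann taper would be a
  straightforward extension. Orientation channels enter as raw degrees
  (mean removal happens only inside the spectral features), configurable
  upstream by centring the channels.

Segments with fewer than 4 samples get `NA` spectral features.
`aggregate_features()` takes min/max/mean/SD of each column over steps with
defined values (feature-major, statistic-minor order; 62 × 4 = 248), with
`NA` SD when fewer than two steps define a column. The registry order is
fixed and serialised identically across runs.

## Fall-risk classification

A random forest on the 248-entry vectors. Published hyperparameters are not
available, so: 500 trees, unlimited depth, inverse-frequency class weights,
stratified 5-fold participant-level CV, per-fold training-median imputation
of undefined entries (no leakage). The forest is `ranger`, seeded and
single-threaded for bit-reproducibility. Whether the original evaluation
used cross-validation or a fixed split is not stated in the source; CV is
the defensible default and is what `evaluate_fall_risk()` reports, as a
pooled confusion matrix with rows = true class, fall risk first.

## Pipeline and problem sizes

`run_pipeline()` chains everything on a synthetic cohort, reproducibly from
one seed: mode `"six_minute"` trains the detector on full trials,
`"two_minute"` on the validation span only (emulating the design in which a
model trained on long walks is applied to short ones, and its short-trained
counterpart underperforms). Fall-risk features come from the heuristic
("manual") strikes for all participants; automated-strike features are
computed for the held-out participants of the single train/test split —
full nested CV of the detector inside the fall-risk CV would multiply cost
without changing what the synthetic cohort can demonstrate. Per-trial
counters (raw predictions, consolidations, insertions, final strikes)
support exactly the failure diagnosis that matters clinically: a trial
whose detected-step count collapses below half the cohort average cannot
support stride-based features.

The bundled experiments use deliberately modest sizes — 60 s trials,
cohorts of 20–30, 5 training epochs, 100-seed labelling replicates — chosen
so the whole suite re-runs in minutes on one core; every size is a
parameter, and nothing in the design caps scale.

## Known limitations

* The simulator's pulse morphology is idealised; detector performance on it
  is an upper bound, not a clinical estimate.
* Foot laterality from a single pelvis sensor is a convention, not a
  measurement.
* The heuristic labeller replaces human raters; its thresholds are
  simulator-calibrated and have no inter-rater validation.
* Turn detection, toe-off events, and contact-force estimation are out of
  scope.
* The printed clinical results (six- and two-minute detector confusion
  matrices, fall-risk matrices, measured stride differences) are outcomes
  of a private cohort; this package reproduces their evaluation arithmetic
  exactly and substitutes property-based synthetic experiments for the rest.
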