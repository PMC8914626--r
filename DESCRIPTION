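Package: stridetect
Title: Foot-Strike Detection, Stride Parameters and Fall-Risk
    Classification from Smartphone Walk Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gait analysis pipeline for pelvis-mounted smartphone IMU
    recordings from two- and six-minute walk tests. Provides signal
    preprocessing (uniform resampling, zero-lag low-pass Butterworth
    filtering, truncation), a deterministic peak-sequence heuristic for
    ground-truth foot-strike labelling, an LSTM sequence classifier over
    31-frame signal windows for automated foot-strike detection,
    rule-based post-processing (consolidation of consecutive predictions,
    adaptive-locking insertion of missed steps), tolerance-matched event
    evaluation, stride parameters (step time, stride time, cadence) with
    minimal-detectable-change comparison, a 62-feature/248-aggregate
    step-based feature set, and random-forest fall-risk classification.
    Includes a synthetic gait simulator producing 12-channel IMU
    recordings with exact foot-strike ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    ranger,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
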