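test_that("segmentation tiles the strike span half-open", {
  p <- prep_trial(gait_sim_config(duration = 30, seed = 21))
  idx <- p$truth$indices
  segs <- segment_steps(p$rec, p$truth)
  expect_length(segs, length(idx) - 1L)
  lens <- vapply(segs, function(s) nrow(s$channels), 0L)
  expect_identical(sum(lens), idx[length(idx)] - idx[1])
  expect_identical(vapply(segs, `[[`, 0L, "start_index"),
                   idx[-length(idx)])
  expect_error(segment_steps(p$rec, idx[1:2]),
               class = "stridetect_validation_error")
})

test_that("the feature table has the fixed 62-column registry", {
  expect_length(feature_registry(), 62L)
  expect_length(participant_feature_names(), 248L)
  # registry composition: 5 temporal, 27 descriptive, 30 spectral
  reg <- feature_registry()
  expect_identical(reg[1:5], c("cadence", "step_time_right", "step_time_left",
                               "stride_time", "symmetry_index"))
  expect_length(grep("fft|reoh", reg), 30L)

  p <- prep_trial(gait_sim_config(duration = 30, seed = 22))
  tab <- compute_step_features(segment_steps(p$rec, p$truth), 50)
  expect_identical(ncol(tab), 62L)
  expect_identical(names(tab), reg)
  expect_identical(nrow(tab), length(p$truth$indices) - 1L)
})

test_that("descriptive statistics match closed forms on constant segments", {
  seg <- structure(list(
    channels = matrix(-2.5, nrow = 20, ncol = 6,
                      dimnames = list(NULL, c("ml", "ap", "vert", "tilt",
                                              "rotation", "obliquity"))),
    foot = "left", duration = 0.4, start_index = 1L),
    class = "step_segment")
  seg2 <- seg; seg2$foot <- "right"; seg2$duration <- 0.5
  tab <- compute_step_features(list(seg, seg2), 50)
  expect_equal(tab$rms_ap, c(2.5, 2.5))     # RMS = |c|
  expect_equal(tab$sd_ml, c(0, 0))
  expect_equal(tab$range_tilt, c(0, 0))
  expect_equal(tab$mean_vert, c(-2.5, -2.5))
  expect_equal(tab$min_ap, c(-2.5, -2.5))
  expect_equal(tab$cadence, c(60 / 0.4, 60 / 0.5))
  # second step has seen both feet: stride time = 0.4 + 0.5
  expect_equal(tab$stride_time[2], 0.9)
  expect_equal(tab$symmetry_index[2],
               symmetry_index(0.5, 0.4))
})

test_that("spectral features agree with a direct DFT oracle", {
  rate <- 50
  n <- 50
  t <- (0:(n - 1)) / rate
  x <- sin(2 * pi * 2 * t)   # pure 2 Hz, exactly on a bin
  ch <- matrix(rep(x, 6), ncol = 6,
               dimnames = list(NULL, c("ml", "ap", "vert", "tilt",
                                       "rotation", "obliquity")))
  seg <- structure(list(channels = ch, foot = "left", duration = 0.5,
                        start_index = 1L), class = "step_segment")
  segR <- seg; segR$foot <- "right"
  tab <- compute_step_features(list(seg, segR), rate)

  # independent oracle: raw DFT magnitudes of the mean-removed signal
  xd <- x - mean(x)
  mag <- Mod(fft(xd))[2:(n / 2 + 1)]
  freqs <- (1:(n / 2)) * rate / n
  expect_equal(tab$max_fft_ap[2], max(mag))
  expect_equal(tab$sd_fft_ap[2], sd(mag))
  expect_equal(tab$peak_distinction_fft_ap[2], max(mag) / mean(mag))
  # median-power frequency of a pure tone is its own bin
  expect_equal(tab$quartile_fft_ap[2], 2)
  pw <- mag^2
  expect_equal(tab$quartile_fft_ap[2],
               freqs[which(cumsum(pw) >= 0.5 * sum(pw))[1]])

  # stride frequency = 1/(0.5+0.5) = 1 Hz; the 2 Hz tone sits on the 2nd
  # (even) harmonic, so even/odd magnitude ratio is large
  expect_gt(tab$reoh_ap[2], 10)

  # conversely a tone on the 1st (odd) harmonic pushes REOH toward 0
  x1 <- sin(2 * pi * 1 * t)
  ch1 <- ch; ch1[] <- rep(x1, 6)
  segA <- seg; segA$channels <- ch1
  segB <- segR; segB$channels <- ch1
  tab1 <- compute_step_features(list(segA, segB), rate)
  expect_lt(tab1$reoh_ap[2], 0.1)
})

test_that("degenerate segments flag spectral features as undefined", {
  ch <- matrix(1.0, nrow = 3, ncol = 6,
               dimnames = list(NULL, c("ml", "ap", "vert", "tilt",
                                       "rotation", "obliquity")))
  seg <- structure(list(channels = ch, foot = "left", duration = 0.06,
                        start_index = 1L), class = "step_segment")
  tab <- compute_step_features(list(seg), 50)
  expect_true(is.na(tab$quartile_fft_ap))
  expect_true(is.na(tab$reoh_vert))
  expect_equal(tab$rms_ap, 1)  # descriptive stats still defined
})

test_that("symmetry index has its closed form and is side-symmetric", {
  expect_equal(symmetry_index(0.5, 0.5), 0)
  expect_equal(symmetry_index(0.6, 0.4), 40)
  expect_equal(symmetry_index(0.4, 0.6), symmetry_index(0.6, 0.4))
  expect_error(symmetry_index(0, 0.5), class = "stridetect_validation_error")
})

test_that("aggregation produces the ordered 248-vector with sane bounds", {
  p <- prep_trial(gait_sim_config(duration = 40, seed = 23))
  tab <- compute_step_features(segment_steps(p$rec, p$truth), 50)
  vec <- aggregate_features(tab)
  expect_length(vec, 248L)
  expect_identical(names(vec), participant_feature_names())
  for (feat in feature_registry()) {
    mn <- vec[paste0(feat, "_min")]; mx <- vec[paste0(feat, "_max")]
    av <- vec[paste0(feat, "_mean")]; s <- vec[paste0(feat, "_sd")]
    expect_true(is.na(av) || (mn <= av + 1e-12 && av <= mx + 1e-12))
    expect_true(is.na(s) || s >= 0)
  }
  # mean entries match an independent recomputation from the table
  man <- vapply(feature_registry(), function(cn) {
    v <- tab[[cn]]; mean(v[is.finite(v)])
  }, numeric(1))
  expect_equal(unname(vec[paste0(feature_registry(), "_mean")]), unname(man))

  # all steps identical -> min = max = mean, sd = 0
  one <- tab[rep(5, 4), ]
  v1 <- aggregate_features(one)
  for (feat in c("cadence", "rms_ap", "max_fft_vert")) {
    expect_equal(v1[paste0(feat, "_min")], v1[paste0(feat, "_max")],
                 ignore_attr = TRUE)
    expect_equal(v1[paste0(feat, "_sd")], 0, ignore_attr = TRUE)
  }
  # RMS >= |mean| per segment
  expect_true(all(tab$rms_ap >= abs(tab$mean_ap) - 1e-12))
})
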