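test_that("recording CSV round-trips and the writer is a fixed point", {
  rec <- make_ramp_recording(n = 50)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, f1)
  back <- read_recording(f1, participant_id = "ramp")
  expect_equal(back$timestamps, rec$timestamps, tolerance = 1e-8)
  expect_equal(back$channels, rec$channels, tolerance = 1e-8)
  write_recording(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("reader reports missing columns and bad timestamps", {
  rec <- make_ramp_recording(n = 10)
  f <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, f)
  df <- read.csv(f)
  df$gx <- NULL
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f2, row.names = FALSE)
  expect_error(read_recording(f2), class = "stridetect_format_error")
  expect_error(read_recording(f2), "gx")

  df2 <- read.csv(f)
  df2$time_s[5] <- df2$time_s[3]
  write.csv(df2, f2, row.names = FALSE)
  err <- tryCatch(read_recording(f2), error = function(e) conditionMessage(e))
  expect_match(err, "index: 5")
})

test_that("axis convention maps device axes to body axes with signs", {
  n <- 5
  df <- data.frame(time_s = seq(0, by = 0.02, length.out = n),
                   ax_raw = 0, ay_raw = 0, az_raw = 0,
                   ax_lin = 1:n, ay_lin = (1:n) * 10, az_lin = (1:n) * 100,
                   gx = 0, gy = 0, gz = 0,
                   tilt = 0, obliquity = 0, rotation = 0)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  rec <- read_recording(f, axis_convention(ap = "-y", ml = "+z", vert = "+x"))
  expect_equal(channel(rec, "ap"), -(1:n) * 10)
  expect_equal(channel(rec, "ml"), (1:n) * 100)
  expect_equal(channel(rec, "vert"), as.numeric(1:n))
  expect_error(axis_convention(ap = "+x", ml = "+x", vert = "+y"),
               class = "stridetect_validation_error")
})

test_that("resampling yields the documented grid and is exact on ramps", {
  # 120 s span at 50 Hz -> 6001 grid points, truncation to 120 s -> 6000
  t <- seq(0, 120, by = 0.01)
  ch <- matrix(1, length(t), 12, dimnames = list(NULL, imu_channels()))
  rec <- imu_recording(t, ch)
  rs <- resample_uniform(rec, 50)
  expect_identical(n_samples(truncate_recording(rs, 120)), 6000L)
  expect_lt(max(abs(diff(diff(rs$timestamps)))), 1e-9)

  # linear ramp recovered exactly under irregular sampling
  ramp <- make_ramp_recording(n = 300)
  rr <- resample_uniform(ramp, 50)
  for (ch_name in c("ap", "rotation")) {
    k <- match(ch_name, imu_channels())
    expect_equal(channel(rr, ch_name), 0.5 * k * rr$timestamps - k,
                 tolerance = 1e-10)
  }

  # already-uniform input is reproduced
  rs2 <- resample_uniform(rs, 50)
  expect_equal(rs2$channels, rs$channels, tolerance = 1e-9)
  expect_error(resample_uniform(rs, -1), class = "stridetect_validation_error")
})

test_that("truncation keeps samples strictly before the cut", {
  t <- (0:18049) / 50  # spans 360.98 s
  ch <- matrix(0, length(t), 12, dimnames = list(NULL, imu_channels()))
  rec <- imu_recording(t, ch)
  expect_identical(n_samples(truncate_recording(rec, 360.98)), 18049L)
  expect_identical(n_samples(truncate_recording(rec, 1000)), 18050L)
})

test_that("truncate and resample commute on uniform-rate inputs", {
  rec <- resample_uniform(make_ramp_recording(n = 500), 50)
  a <- truncate_recording(resample_uniform(rec, 25), 5)
  b <- resample_uniform(truncate_recording(rec, 5), 25)
  expect_equal(a$timestamps, b$timestamps, tolerance = 1e-9)
  expect_equal(a$channels, b$channels, tolerance = 1e-9)
})

test_that("zero-lag filter matches the analytic forward-backward response", {
  for (method in c("freq", "filtfilt")) {
    const <- make_sinusoid_recording(1, amp = 0)
    const$channels[] <- 3.7
    out <- lowpass_zero_lag(const, 4, 4, method = method)
    expect_equal(channel(out, "ap"), rep(3.7, n_samples(const)),
                 tolerance = 1e-6)
  }

  # stop band: measured amplitude of a 10 Hz sinusoid vs 1/(1+(10/4)^8)
  rec10 <- lowpass_zero_lag(make_sinusoid_recording(10), 4, 4)
  mid <- seq(round(0.25 * n_samples(rec10)), round(0.75 * n_samples(rec10)))
  amp10 <- fitted_amplitude(channel(rec10, "ap")[mid],
                            rec10$timestamps[mid], 10)
  expect_lt(abs(amp10 - 1 / (1 + 2.5^8)), 0.2 / (1 + 2.5^8))

  # pass band: 1 Hz gain
  rec1 <- lowpass_zero_lag(make_sinusoid_recording(1), 4, 4)
  amp1 <- fitted_amplitude(channel(rec1, "ap")[mid], rec1$timestamps[mid], 1)
  expect_gte(amp1, 0.999)

  expect_error(lowpass_zero_lag(make_ramp_recording(), 4, 4),
               class = "stridetect_precondition_error")
  expect_error(lowpass_zero_lag(make_sinusoid_recording(1), cutoff = 30),
               class = "stridetect_precondition_error")
})

test_that("zero-lag filtering introduces no phase shift", {
  rec <- make_sinusoid_recording(1)
  for (method in c("freq", "filtfilt")) {
    y <- channel(lowpass_zero_lag(rec, 4, 4, method = method), "ap")
    x <- channel(rec, "ap")
    lags <- -5:5
    xc <- vapply(lags, function(l) {
      i <- seq(50, n_samples(rec) - 50)
      sum(x[i] * y[i + l])
    }, numeric(1))
    expect_identical(lags[which.max(xc)], 0L)
  }
})

test_that("label files round-trip in both formats", {
  idx <- c(3L, 50L, 51L, 400L)
  f <- withr::local_tempfile()
  write_labels(idx, f)
  expect_identical(read_labels(f), idx)
  writeLines(c("index,time_s", paste(idx, idx / 50, sep = ",")), f)
  expect_identical(read_labels(f), idx)
})
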