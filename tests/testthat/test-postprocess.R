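test_that("runs of consecutive predictions collapse to the AP peak", {
  ap <- rep(0, 200)
  ap[c(100, 101, 102)] <- c(1, 3, 2)
  out <- consolidate_runs(c(100L, 101L, 102L), ap)
  expect_identical(out$indices, 101L)
  # isolated predictions pass through
  expect_identical(consolidate_runs(50L, ap)$indices, 50L)
  # two separate runs give exactly one index per run
  ap2 <- rep(0, 200); ap2[c(10, 11, 40, 41, 42)] <- c(2, 1, 1, 5, 2)
  out2 <- consolidate_runs(c(10L, 11L, 40L, 41L, 42L), ap2)
  expect_identical(out2$indices, c(10L, 41L))

  # random fixtures: output count equals the number of maximal runs and no
  # two outputs remain adjacent
  set.seed(11)
  for (i in 1:25) {
    idx <- sort(sample(300, 40))
    ap_r <- runif(300)
    out_r <- consolidate_runs(idx, ap_r)
    n_runs <- sum(diff(idx) != 1L) + 1L
    expect_length(out_r$indices, n_runs)
    expect_true(all(diff(out_r$indices) > 1L))
  }
})

test_that("missed steps are inserted at the AP peak inside the locking window", {
  # strikes at 10.0, 11.0, 13.2 s at 50 Hz; constructed AP peak at 12.1 s
  rate <- 50
  ap <- rep(0, 800)
  peak_at <- function(t) as.integer(round(t * rate)) + 1L
  ap[peak_at(12.1)] <- 2
  pred <- peak_at(c(10, 11, 13.2))
  out <- insert_missed_steps(pred, ap, rate)
  expect_identical(out$indices, sort(c(pred, peak_at(12.1))))

  # uniform strikes: nothing qualifies
  uni <- peak_at(seq(2, 12, by = 0.8))
  expect_identical(insert_missed_steps(uni, ap, rate)$indices, uni)

  # existing predictions are never removed; step times respect the margin
  expect_true(all(pred %in% out$indices))
  durs <- diff(out$indices)
  expect_true(all(durs >= 0.4 * 50 * 1.0 - 1))

  expect_warning(out1 <- insert_missed_steps(42L, ap, rate),
                 "fewer than 2")
  expect_identical(out1$indices, 42L)
})

test_that("deleted strikes are restored and postprocessing is idempotent", {
  restored <- 0L; total <- 0L
  for (s in 1:10) {
    p <- prep_trial(gait_sim_config(duration = 60, seed = 600 + s))
    idx <- p$truth$indices
    del <- seq(5, length(idx), by = 5)
    out <- insert_missed_steps(idx[-del], channel(p$rec, "ap"), 50)
    ok <- vapply(idx[del], function(d) any(abs(out$indices - d) <= 2),
                 logical(1))
    restored <- restored + sum(ok); total <- total + length(ok)

    # idempotence of the full chain on simulator fixtures
    ap <- channel(p$rec, "ap")
    once <- postprocess_predictions(idx[-del], ap, 50)
    twice <- postprocess_predictions(once, ap, 50)
    expect_identical(twice$indices, once$indices)
  }
  expect_gte(restored / total, 0.9)
})

test_that("multi-pass insertion fills gaps spanning several missed steps", {
  rate <- 50
  true_t <- seq(2, 20, by = 0.5)
  ap <- rep(0, 1100)
  idx <- round(true_t * rate) + 1L
  ap[idx] <- 2 + 0.1 * sin(seq_along(idx))
  # delete a block of 3 consecutive strikes
  kept <- idx[-(10:12)]
  out <- insert_missed_steps(kept, ap, rate)
  expect_true(all(vapply(idx[10:12], function(d) {
    any(abs(out$indices - d) <= 2)
  }, logical(1))))
})

test_that("postprocessing parameters are validated", {
  expect_error(postprocess_params(gap_factor = 1), class = "stridetect_validation_error")
  expect_error(postprocess_params(locking_margin = 0.5), class = "stridetect_validation_error")
  expect_error(postprocess_params(max_passes = 0), class = "stridetect_validation_error")
})
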