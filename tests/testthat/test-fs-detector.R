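test_that("window construction follows the 31-frame edge rules", {
  p <- prep_trial(gait_sim_config(duration = 125, seed = 1))
  rec <- truncate_recording(p$rec, 120)
  truth <- labels_from_times(p$trial$true_fs_times, rec)
  expect_identical(n_samples(rec), 6000L)
  ws <- build_windows(rec, truth)
  expect_identical(dim(ws$windows), c(31L, 6000L, 12L))
  x <- rec$channels
  # first anchor: frames 1..31; last anchor: frames N-30..N; interior: i +/- 15
  expect_equal(ws$windows[, 1, ], x[1:31, ], ignore_attr = TRUE)
  expect_equal(ws$windows[, 6000, ], x[5970:6000, ], ignore_attr = TRUE)
  expect_equal(ws$windows[, 15, ], x[15:45, ], ignore_attr = TRUE)
  expect_equal(ws$windows[, 16, ], x[1:31, ], ignore_attr = TRUE)
  expect_equal(ws$windows[, 5985, ], x[5970:6000, ], ignore_attr = TRUE)
  expect_equal(ws$windows[, 3000, ], x[2985:3015, ], ignore_attr = TRUE)
  expect_identical(sum(ws$labels), length(truth$indices))
  # anchor signal reconstruction honours the edge rules
  expect_equal(center_signal(ws, "ap"), channel(rec, "ap"), ignore_attr = TRUE)
  expect_error(build_windows(rec$channels[1:20, ], integer(20)),
               class = "stridetect_validation_error")
})

test_that("tolerance matching agrees with the exhaustive oracle", {
  # spec examples
  cm <- match_with_tolerance(100L, 102L, 2, 200)
  expect_identical(c(cm$tp, cm$fn, cm$fp, cm$tn), c(1L, 0L, 0L, 199L))
  cm <- match_with_tolerance(100L, 103L, 2, 200)
  expect_identical(c(cm$tp, cm$fn, cm$fp), c(0L, 1L, 1L))
  cm <- match_with_tolerance(c(100L, 104L), 102L, 2, 200)
  expect_identical(c(cm$tp, cm$fn, cm$fp), c(1L, 1L, 0L))

  set.seed(7)
  for (i in 1:300) {
    nt <- sample(0:8, 1); np <- sample(0:8, 1)
    tol <- sample(0:3, 1)
    truth <- sort(sample(60, nt))
    pred <- sort(sample(60, np))
    cm <- match_with_tolerance(truth, pred, tol, 60)
    expect_identical(cm$tp, oracle_max_matching(truth, pred, tol))
    expect_identical(cm$tp + cm$fn, length(truth))
    expect_identical(cm$tp + cm$fp, length(pred))
  }
  expect_error(match_with_tolerance(1L, 1L, -1, 10),
               class = "stridetect_validation_error")
})

test_that("metrics reproduce printed foot-strike confusion matrices", {
  m6 <- compute_metrics(confusion_matrix(11283, 1025, 2361, 386010))
  expect_equal(unlist(m6), c(accuracy = 99.2, sensitivity = 91.7,
                                 specificity = 99.4, precision = 82.7))
  m2 <- compute_metrics(confusion_matrix(8006, 4302, 3672, 383200))
  expect_equal(unlist(m2), c(accuracy = 98.0, sensitivity = 65.0,
                                 specificity = 99.1, precision = 68.6))
  perfect <- compute_metrics(confusion_matrix(10, 0, 0, 90))
  expect_true(all(unlist(perfect) == 100))
  undef <- compute_metrics(confusion_matrix(0, 0, 0, 90))
  expect_true(is.na(undef$sensitivity))
  expect_true(is.na(undef$precision))
  expect_equal(undef$accuracy, 100)
})

test_that("LSTM gradients match finite differences", {
  set.seed(42)
  par <- stridetect:::init_lstm_params(2, 3, 2)
  X <- array(rnorm(4 * 3 * 2), dim = c(4, 3, 2))
  y <- c(1, 0, 1); w <- c(2, 1, 1)
  lg <- stridetect:::lstm_loss_grads(par, X, y, w)
  num_grad <- function(nm, i) {
    eps <- 1e-6
    p1 <- par; p1[[nm]][i] <- p1[[nm]][i] + eps
    p2 <- par; p2[[nm]][i] <- p2[[nm]][i] - eps
    (stridetect:::lstm_loss_grads(p1, X, y, w)$loss -
       stridetect:::lstm_loss_grads(p2, X, y, w)$loss) / (2 * eps)
  }
  for (nm in names(lg$grads)) {
    for (i in seq_len(min(8, length(lg$grads[[nm]])))) {
      expect_equal(lg$grads[[nm]][i], num_grad(nm, i), tolerance = 1e-5)
    }
  }
})

test_that("the sequence model separates a trivially separable fixture", {
  ws <- make_toy_window_set(200)
  cfg <- fs_model_config(lstm_units = 8, dense_units = 4, epochs = 30,
                         learning_rate = 5e-3, dropout = 0,
                         negative_ratio = Inf, seed = 3)
  m <- train_fs_model(ws, cfg)
  p <- predict_fs_prob(m, ws)
  expect_identical(as.integer(p >= 0.5), ws$labels)
  # spec'd thresholds: 0 labels everything, > 1 labels nothing
  expect_length(predict_fs(m, ws, threshold = 1 + 1e-9)$indices, 0)
  expect_length(predict_fs(m, ws, threshold = 0)$indices, 200L)
  # exact FS centers at the default threshold on the separable fixture
  expect_identical(predict_fs(m, ws)$indices, which(ws$labels == 1L))
  # training history is retrievable and decreasing overall
  expect_length(m$history, 30)
  expect_lt(m$history[30], m$history[1])
  # config is echoed on the handle
  expect_identical(m$config$lstm_units, 8L)

  only_pos <- ws; only_pos$labels <- rep(1L, 200)
  expect_error(train_fs_model(only_pos, cfg),
               class = "stridetect_validation_error")
  bad <- make_toy_window_set(64)
  bad$windows <- bad$windows[, , 1:6]
  expect_error(predict_fs_prob(m, bad), class = "stridetect_validation_error")
})

test_that("default model configuration matches the published architecture", {
  cfg <- fs_model_config()
  expect_identical(cfg$lstm_units, 100L)
  expect_identical(cfg$dense_units, 50L)
  expect_identical(cfg$batch_size, 64L)
  expect_identical(cfg$dropout, 0.4)
})

test_that("cross-validation partitions by participant and pools additively", {
  trials <- lapply(1:6, function(s) {
    p <- prep_trial(gait_sim_config(duration = 20, seed = 400 + s))
    list(windows = build_windows(p$rec, p$truth), truth = p$truth)
  })
  oracle <- function(train_trials, test_windows) {
    foot_strike_labels(which(test_windows$labels == 1L), "model")
  }
  cv <- cross_validate(trials, k = 3, config = fs_model_config(seed = 2),
                       detector = oracle, postprocess = FALSE)
  expect_identical(sort(unique(cv$fold_assignment)), 1:3)
  expect_identical(as.vector(table(cv$fold_assignment)), rep(2L, 3))
  expect_identical(cv$pooled_matrix$tp,
                   sum(vapply(cv$fold_matrices, `[[`, 0L, "tp")))
  expect_true(all(unlist(cv$pooled_metrics) == 100))
  expect_error(cross_validate(trials, k = 7), class = "stridetect_validation_error")
})
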