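# LSTM sequence classifier for per-sample foot-strike detection.
#
# A single LSTM layer read out at the last frame, a ReLU dense layer, and a
# sigmoid output, trained with weighted binary cross-entropy and Adam. The
# implementation is self-contained: batched forward pass, backpropagation
# through time, inverted dropout on the LSTM output, all as BLAS-backed
# matrix operations. Gradients are verified against finite differences in
# the test suite.

#' Configuration of the foot-strike sequence model
#'
#' Defaults follow the published configuration: 100 LSTM units, a 50-unit
#' dense layer, batch size 64, dropout 0.4. Epoch count, optimizer (Adam,
#' learning rate 1e-3) and the training-set composition are this package's
#' own documented choices.
#'
#' @param lstm_units hidden units in the LSTM layer.
#' @param dense_units hidden units in the dense layer.
#' @param batch_size minibatch size.
#' @param dropout dropout probability on the LSTM output during training.
#' @param epochs training epochs.
#' @param learning_rate Adam learning rate.
#' @param class_weighting `"inverse_frequency"` (weights each class by
#'   total/(2 x class count), countering the ~3% positive rate) or `"none"`.
#' @param negative_ratio negatives kept per positive window when assembling
#'   the training set (`Inf` keeps every window). Windows within
#'   `hard_negative_radius` frames of a strike are always kept: they are the
#'   near-misses the model must learn to reject.
#' @param hard_negative_radius see `negative_ratio`.
#' @param threshold default probability threshold for prediction.
#' @param seed integer seed for initialisation, subsampling and shuffling.
#' @return an `fs_model_config` object.
#' @export
fs_model_config <- function(lstm_units = 100, dense_units = 50,
                            batch_size = 64, dropout = 0.4, epochs = 8,
                            learning_rate = 1e-3,
                            class_weighting = c("inverse_frequency", "none"),
                            negative_ratio = 4, hard_negative_radius = 5,
                            threshold = 0.5, seed = 1) {
  class_weighting <- match.arg(class_weighting)
  for (f in c(lstm_units, dense_units, batch_size, epochs)) {
    if (!is_count(f)) validation_error("units, batch_size and epochs must be positive integers")
  }
  if (!is.numeric(dropout) || dropout < 0 || dropout >= 1) {
    validation_error("dropout must be in [0, 1)")
  }
  structure(list(lstm_units = as.integer(lstm_units),
                 dense_units = as.integer(dense_units),
                 batch_size = as.integer(batch_size), dropout = dropout,
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 class_weighting = class_weighting,
                 negative_ratio = negative_ratio,
                 hard_negative_radius = as.integer(hard_negative_radius),
                 threshold = threshold, seed = as.integer(seed)),
            class = "fs_model_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

init_lstm_params <- function(d_in, nh, nd) {
  b <- numeric(4 * nh)
  b[(nh + 1):(2 * nh)] <- 1   # forget-gate bias starts open
  list(W = glorot(d_in + nh, 4 * nh), b = b,
       W1 = glorot(nh, nd), b1 = numeric(nd),
       W2 = glorot(nd, 1), b2 = 0)
}

add_row <- function(A, b) A + matrix(b, nrow(A), length(b), byrow = TRUE)

# Forward pass over a batch. X: array T x B x D. Returns probabilities and,
# when `keep_cache`, everything BPTT needs.
lstm_forward <- function(par, X, dropmask = NULL, keep_cache = FALSE) {
  Td <- dim(X)[1]; B <- dim(X)[2]; D <- dim(X)[3]
  nh <- nrow(par$W1)
  ii <- 1:nh; fi <- nh + ii; gi <- 2 * nh + ii; oi <- 3 * nh + ii
  H <- matrix(0, B, nh); C <- matrix(0, B, nh)
  cache <- if (keep_cache) vector("list", Td)
  for (t in seq_len(Td)) {
    Z <- cbind(matrix(X[t, , ], B, D), H)
    A <- add_row(Z %*% par$W, par$b)
    ig <- sigmoid(A[, ii, drop = FALSE])
    fg <- sigmoid(A[, fi, drop = FALSE])
    gg <- tanh(A[, gi, drop = FALSE])
    og <- sigmoid(A[, oi, drop = FALSE])
    Cprev <- C
    C <- fg * C + ig * gg
    tC <- tanh(C)
    H <- og * tC
    if (keep_cache) {
      cache[[t]] <- list(Z = Z, i = ig, f = fg, g = gg, o = og,
                         Cprev = Cprev, tC = tC)
    }
  }
  Hd <- if (is.null(dropmask)) H else H * dropmask
  A1 <- add_row(Hd %*% par$W1, par$b1)
  D1 <- pmax(A1, 0)
  logit <- drop(D1 %*% par$W2) + par$b2
  prob <- sigmoid(logit)
  list(prob = prob, logit = logit,
       cache = if (keep_cache) list(steps = cache, H = H, Hd = Hd, D1 = D1))
}

# Weighted binary cross-entropy loss and full gradients for one batch.
lstm_loss_grads <- function(par, X, y, w, dropmask = NULL) {
  fw <- lstm_forward(par, X, dropmask, keep_cache = TRUE)
  p <- pmin(pmax(fw$prob, 1e-12), 1 - 1e-12)
  sw <- sum(w)
  loss <- -sum(w * (y * log(p) + (1 - y) * log(1 - p))) / sw
  B <- length(y)
  nh <- nrow(par$W1); D <- dim(X)[3]
  dlogit <- matrix((fw$prob - y) * w / sw, B, 1)

  cc <- fw$cache
  dW2 <- crossprod(cc$D1, dlogit)
  db2 <- sum(dlogit)
  dD1 <- tcrossprod(dlogit, par$W2)
  dD1[cc$D1 <= 0] <- 0
  dW1 <- crossprod(cc$Hd, dD1)
  db1 <- colSums(dD1)
  dH <- tcrossprod(dD1, par$W1)
  if (!is.null(dropmask)) dH <- dH * dropmask

  ii <- 1:nh; fi <- nh + ii; gi <- 2 * nh + ii; oi <- 3 * nh + ii
  dW <- matrix(0, nrow(par$W), ncol(par$W)); db <- numeric(length(par$b))
  dC <- matrix(0, B, nh)
  for (t in rev(seq_along(cc$steps))) {
    s <- cc$steps[[t]]
    do_ <- dH * s$tC
    dC <- dC + dH * s$o * (1 - s$tC^2)
    di <- dC * s$g
    dg <- dC * s$i
    df <- dC * s$Cprev
    dA <- cbind(di * s$i * (1 - s$i), df * s$f * (1 - s$f),
                dg * (1 - s$g^2), do_ * s$o * (1 - s$o))
    dW <- dW + crossprod(s$Z, dA)
    db <- db + colSums(dA)
    dZ <- tcrossprod(dA, par$W)
    dH <- dZ[, D + ii, drop = FALSE]
    dC <- dC * s$f
  }
  list(loss = loss,
       grads = list(W = dW, b = db, W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

adam_step <- function(par, grads, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  corr1 <- 1 - b1^st$t; corr2 <- 1 - b2^st$t
  for (nm in names(grads)) {
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * grads[[nm]]
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * grads[[nm]]^2
    par[[nm]] <- par[[nm]] -
      lr * (st$m[[nm]] / corr1) / (sqrt(st$v[[nm]] / corr2) + eps)
  }
  list(par = par, st = st)
}

# Assemble the training windows from one or more window sets: all positives,
# all hard negatives (within `hard_negative_radius` frames of a positive),
# plus random negatives up to `negative_ratio` negatives per positive.
assemble_training_set <- function(sets, config) {
  pick <- lapply(sets, function(ws) {
    pos <- which(ws$labels == 1L)
    neg <- which(ws$labels == 0L)
    if (is.finite(config$negative_ratio)) {
      hard <- integer(0)
      if (length(pos)) {
        hard <- unique(unlist(lapply(pos, function(i) {
          (i - config$hard_negative_radius):(i + config$hard_negative_radius)
        })))
        hard <- setdiff(intersect(hard, neg), pos)
      }
      want <- round(config$negative_ratio * length(pos))
      extra <- setdiff(neg, hard)
      n_extra <- max(0L, want - length(hard))
      if (n_extra < length(extra)) {
        extra <- sort(sample(extra, n_extra))
      }
      neg <- sort(c(hard, extra))
    }
    list(ws = ws, idx = sort(c(pos, neg)))
  })
  X <- do.call(abind3, lapply(pick, function(p) {
    p$ws$windows[, p$idx, , drop = FALSE]
  }))
  y <- unlist(lapply(pick, function(p) p$ws$labels[p$idx]))
  list(X = X, y = y)
}

# bind arrays T x B_i x D along the second dimension
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(0, dim = c(d[1], sum(vapply(parts, function(p) dim(p)[2], 0)),
                          d[3]),
               dimnames = list(NULL, NULL, dimnames(parts[[1]])[[3]]))
  at <- 0L
  for (p in parts) {
    out[, at + seq_len(dim(p)[2]), ] <- p
    at <- at + dim(p)[2]
  }
  out
}

#' Train the foot-strike sequence model
#'
#' @param train a `window_set` or list of `window_set`s (one per trial).
#' @param config an [fs_model_config()].
#' @param verbose print per-epoch loss.
#' @return an `fs_model`: trained parameters, per-channel normalisation
#'   statistics, the config, and the training history (mean weighted loss
#'   per epoch).
#' @export
train_fs_model <- function(train, config = fs_model_config(), verbose = FALSE) {
  if (inherits(train, "window_set")) train <- list(train)
  all_labels <- unlist(lapply(train, `[[`, "labels"))
  if (length(unique(all_labels)) < 2L) {
    validation_error("training data must contain both classes")
  }
  with_seed(config$seed, {
    ts <- assemble_training_set(train, config)
    X <- ts$X; y <- ts$y
    M <- length(y); D <- dim(X)[3]
    # per-channel standardisation (orientation channels are on a degree
    # scale two orders above the accelerations)
    mu <- apply(X, 3, mean)
    sdv <- pmax(apply(X, 3, stats::sd), 1e-8)
    for (c_ in seq_len(D)) X[, , c_] <- (X[, , c_] - mu[c_]) / sdv[c_]

    w_class <- c(1, 1)
    if (config$class_weighting == "inverse_frequency") {
      w_class <- M / (2 * c(sum(y == 0), sum(y == 1)))
    }
    w <- w_class[y + 1L]

    par <- init_lstm_params(D, config$lstm_units, config$dense_units)
    st <- list(t = 0,
               m = lapply(par, function(p) p * 0),
               v = lapply(par, function(p) p * 0))
    history <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(M)
      ep_loss <- 0; ep_w <- 0
      for (b0 in seq(1, M, by = config$batch_size)) {
        bi <- ord[b0:min(b0 + config$batch_size - 1L, M)]
        Xb <- X[, bi, , drop = FALSE]
        mask <- NULL
        if (config$dropout > 0) {
          mask <- matrix(stats::rbinom(length(bi) * config$lstm_units, 1,
                                       1 - config$dropout),
                         length(bi), config$lstm_units) / (1 - config$dropout)
        }
        lg <- lstm_loss_grads(par, Xb, y[bi], w[bi], mask)
        upd <- adam_step(par, lg$grads, st, config$learning_rate)
        par <- upd$par; st <- upd$st
        ep_loss <- ep_loss + lg$loss * sum(w[bi]); ep_w <- ep_w + sum(w[bi])
      }
      history[ep] <- ep_loss / ep_w
      if (verbose) message(sprintf("epoch %d/%d loss %.5f", ep, config$epochs,
                                   history[ep]))
    }
    structure(list(params = par, norm = list(mu = mu, sd = sdv),
                   config = config, history = history, n_train = M),
              class = "fs_model")
  })
}

#' @export
print.fs_model <- function(x, ...) {
  cat(sprintf(
    "<fs_model> LSTM(%d) + dense(%d), batch %d, dropout %.2f; %d epochs on %d windows; final loss %.4f\n",
    x$config$lstm_units, x$config$dense_units, x$config$batch_size,
    x$config$dropout, x$config$epochs, x$n_train,
    x$history[length(x$history)]))
  invisible(x)
}

#' Per-window foot-strike probabilities
#'
#' @param model a trained `fs_model`.
#' @param windows a `window_set`.
#' @param batch prediction batch size.
#' @return numeric vector of probabilities, one per window.
#' @export
predict_fs_prob <- function(model, windows, batch = 512L) {
  X <- windows$windows
  if (dim(X)[1] != 31L || dim(X)[3] != length(model$norm$mu)) {
    validation_error("window shape does not match the trained model")
  }
  for (c_ in seq_len(dim(X)[3])) {
    X[, , c_] <- (X[, , c_] - model$norm$mu[c_]) / model$norm$sd[c_]
  }
  n <- dim(X)[2]
  p <- numeric(n)
  for (b0 in seq(1, n, by = batch)) {
    bi <- b0:min(b0 + batch - 1L, n)
    p[bi] <- lstm_forward(model$params, X[, bi, , drop = FALSE])$prob
  }
  p
}

#' Predict foot-strike labels from a window set
#'
#' @param model a trained `fs_model`.
#' @param windows a `window_set`.
#' @param threshold probability threshold (defaults to the model config's).
#' @return `foot_strike_labels` with `source = "model"`.
#' @export
predict_fs <- function(model, windows, threshold = NULL) {
  if (is.null(threshold)) threshold <- model$config$threshold
  p <- predict_fs_prob(model, windows)
  foot_strike_labels(which(p >= threshold), "model",
                     n_total = dim(windows$windows)[2])
}
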