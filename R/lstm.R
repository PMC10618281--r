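#' Focal loss for binary spike targets
#'
#' The focal loss down-weights easy (confidently classified) bins via the
#' exponent `gamma`, which matters for spike data where almost all bins are
#' zero:
#' `L_F = -sum[ X (1 - pi)^gamma log(pi) + (1 - X) pi^gamma log(1 - pi) ]`.
#' At `gamma = 0` it reduces exactly to the binary cross-entropy.
#' Probabilities are clamped to `[1e-7, 1 - 1e-7]` before the logarithms.
#'
#' @param pi predicted firing probabilities (vector or matrix in `[0, 1]`).
#' @param X binary targets, same shape as `pi`.
#' @param gamma focusing exponent, `>= 0` (default 2).
#' @return the summed loss (a scalar).
#' @export
focal_loss <- function(pi, X, gamma = 2) {
  if (gamma < 0) abort("`gamma` must be >= 0.")
  if (length(pi) != length(X)) {
    abort(sprintf("shape mismatch: `pi` has %d elements, `X` has %d.",
                  length(pi), length(X)))
  }
  if (!all(X %in% c(0, 1))) abort("`X` must be binary.")
  eps <- 1e-7
  p <- pmin(pmax(as.numeric(pi), eps), 1 - eps)
  x <- as.numeric(X)
  -sum(x * (1 - p)^gamma * log(p) + (1 - x) * p^gamma * log(1 - p))
}

#' Multilayer LSTM configuration
#'
#' The full-scale configuration is 3 hidden LSTM layers of 128 units (five
#' layers counting input and output), focal-loss exponent `gamma = 2`,
#' 350 epochs, batch size 64, and the Adam optimizer; training windows are
#' non-overlapping sweeps of `window_len` bins. Scaled-down values are used
#' for desk-size runs (see [pipeline_config()]).
#'
#' @param input_dim number of neurons (input and output dimension).
#' @param n_hidden_layers number of LSTM layers (default 3).
#' @param hidden_units LSTM units per layer (default 128).
#' @param gamma focal-loss exponent (default 2).
#' @param epochs training epochs (default 350).
#' @param batch_size windows per gradient step (default 64).
#' @param window_len training window length in bins (default 256).
#' @param stride distance between successive training-window starts in bins
#'   (default `window_len`, i.e. non-overlapping sweeps). Overlapping
#'   windows (`stride < window_len`) multiply the gradient steps per epoch,
#'   which short training schedules need to move beyond bias fitting.
#' @param threshold_h generation threshold in (0, 1), or `NULL` to calibrate
#'   against the training spike count (the default).
#' @param lr Adam learning rate (default 1e-3).
#' @param clip_norm global gradient-norm clip (default 5; 0 disables).
#' @param val_frac fraction of training windows (the last ones in time) held
#'   out for the validation-loss trace (default 0.1).
#' @param seed RNG seed for weight initialisation and window shuffling.
#' @return list of class `lstm_config`.
#' @export
lstm_config <- function(input_dim, n_hidden_layers = 3, hidden_units = 128,
                        gamma = 2, epochs = 350, batch_size = 64,
                        window_len = 256, stride = window_len,
                        threshold_h = NULL, lr = 1e-3,
                        clip_norm = 5, val_frac = 0.1, seed = NULL) {
  if (gamma < 0) abort("`gamma` must be >= 0.")
  if (epochs < 1) abort("`epochs` must be >= 1.")
  if (window_len < 2) abort("`window_len` must be >= 2.")
  if (stride < 1) abort("`stride` must be >= 1.")
  if (!is.null(threshold_h) && (threshold_h <= 0 || threshold_h >= 1)) {
    abort("`threshold_h` must lie strictly between 0 and 1.")
  }
  structure(
    list(input_dim = as.integer(input_dim),
         n_hidden_layers = as.integer(n_hidden_layers),
         hidden_units = as.integer(hidden_units), gamma = gamma,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         window_len = as.integer(window_len), stride = as.integer(stride),
         threshold_h = threshold_h,
         optimizer = "adam", lr = lr, clip_norm = clip_norm,
         val_frac = val_frac, seed = seed),
    class = "lstm_config"
  )
}

init_lstm_params <- function(config, base_rate = NULL) {
  H <- config$hidden_units
  s <- 1 / sqrt(H)
  layers <- vector("list", config$n_hidden_layers)
  d <- config$input_dim
  for (l in seq_len(config$n_hidden_layers)) {
    b <- rep(0, 4 * H)
    b[(H + 1):(2 * H)] <- 1  # forget-gate bias: start remembering
    layers[[l]] <- list(
      W = matrix(runif(d * 4 * H, -s, s), d, 4 * H),
      U = matrix(runif(H * 4 * H, -s, s), H, 4 * H),
      b = b
    )
    d <- H
  }
  c_out <- rep(0, config$input_dim)
  if (!is.null(base_rate)) {
    p <- pmin(pmax(base_rate, 1e-5), 1 - 1e-5)
    c_out <- log(p / (1 - p))  # prior-matched output bias for rare spikes
  }
  list(layers = layers,
       V = matrix(runif(H * config$input_dim, -s, s), H, config$input_dim),
       c = c_out)
}

#' Train the next-step spike predictor
#'
#' Slides non-overlapping windows of `window_len` bins over the training
#' raster; for each window the network reads bins `t` and predicts the
#' firing-probability vector for bin `t + 1`. Parameters are fit with Adam
#' on the mean focal loss, hidden state reset at each window. The last
#' `val_frac` of windows (in time) are held out and only scored, giving the
#' validation trace. Deterministic given `config$seed`.
#'
#' @param train_raster a [spike_raster()] with `input_dim` neurons.
#' @param config an [lstm_config()].
#' @return object of class `lstm_model`: trained parameters, the config, the
#'   training raster's neuron metadata and spike count, and `trace`, a tibble
#'   with per-epoch `train_loss` and `val_loss` (mean focal loss per
#'   matrix element).
#' @export
train_lstm <- function(train_raster, config) {
  stopifnot(inherits(train_raster, "spike_raster"),
            inherits(config, "lstm_config"))
  if (n_neurons(train_raster) != config$input_dim) {
    abort(sprintf("raster has %d neurons but config expects %d.",
                  n_neurons(train_raster), config$input_dim))
  }
  T_total <- n_bins(train_raster)
  wl <- config$window_len
  if (T_total < wl + 1) abort("training raster shorter than one window.")
  starts <- seq(0L, T_total - 1L - wl, by = config$stride)
  n_val <- floor(config$val_frac * length(starts))
  if (length(starts) - n_val < 1) abort("no training windows left after the validation split.")
  val_starts <- if (n_val > 0) tail(starts, n_val) else integer(0)
  train_starts <- head(starts, length(starts) - n_val)

  X <- matrix(as.numeric(train_raster$X), nrow = T_total)
  fit <- with_seed(config$seed, {
    params <- init_lstm_params(config, base_rate = colMeans(X))
    orders <- t(vapply(seq_len(config$epochs),
                       function(e) sample.int(length(train_starts)) - 1L,
                       integer(length(train_starts))))
    lstm_train_core(X, params, orders, as.integer(train_starts),
                    as.integer(val_starts), wl, config$batch_size,
                    config$gamma, config$lr, config$clip_norm)
  })
  structure(
    list(params = fit$params, config = config,
         neurons = train_raster$neurons, bin_ms = train_raster$bin_ms,
         train_spikes = sum(train_raster$X), train_bins = T_total,
         trace = tibble(epoch = seq_len(config$epochs),
                        train_loss = as.numeric(fit$train_loss),
                        val_loss = as.numeric(fit$val_loss))),
    class = "lstm_model"
  )
}

#' @export
print.lstm_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<lstm_model> %d hidden layers x %d units, %d neurons, gamma = %g\n",
    cfg$n_hidden_layers, cfg$hidden_units, cfg$input_dim, cfg$gamma))
  cat(sprintf("  trained %d epochs; final train loss %.4g, val loss %.4g\n",
              nrow(x$trace), tail(x$trace$train_loss, 1),
              tail(x$trace$val_loss, 1)))
  invisible(x)
}

#' @export
tidy.lstm_model <- function(x, ...) x$trace

#' @export
glance.lstm_model <- function(x, ...) {
  tibble(
    n_hidden_layers = x$config$n_hidden_layers,
    hidden_units = x$config$hidden_units,
    input_dim = x$config$input_dim,
    gamma = x$config$gamma,
    epochs = nrow(x$trace),
    final_train_loss = tail(x$trace$train_loss, 1),
    final_val_loss = tail(x$trace$val_loss, 1)
  )
}

#' Teacher-forced one-step firing probabilities
#'
#' Runs the trained network over the test raster feeding the TRUE test bins
#' (never its own output), with the hidden state carried across the whole
#' sequence. The first `warmup` bins are consumed as context only; the
#' output has one probability row for every later bin, row `k` predicting
#' test bin `warmup + k` from the true bins before it.
#'
#' @param model an [train_lstm()] model.
#' @param test_raster a [spike_raster()] with the model's `input_dim`
#'   neurons.
#' @param warmup context bins before the first prediction (default: the
#'   training `window_len`).
#' @return object of class `firing_prob`: probability matrix `pi`
#'   (rows = predicted bins, columns = neurons), the `offset` (= warmup),
#'   neuron metadata and timing.
#' @export
predict_probabilities <- function(model, test_raster,
                                  warmup = model$config$window_len) {
  stopifnot(inherits(model, "lstm_model"), inherits(test_raster, "spike_raster"))
  if (n_neurons(test_raster) != model$config$input_dim) {
    abort(sprintf("test raster has %d neurons but the model expects %d.",
                  n_neurons(test_raster), model$config$input_dim))
  }
  if (n_bins(test_raster) < warmup + 1) {
    abort(sprintf("test raster too short: %d bins, need > warmup = %d.",
                  n_bins(test_raster), warmup))
  }
  X <- matrix(as.numeric(test_raster$X), nrow = n_bins(test_raster))
  pi <- lstm_predict_core(model$params, X, as.integer(warmup))
  structure(
    list(pi = pi, offset = as.integer(warmup),
         neurons = test_raster$neurons, bin_ms = test_raster$bin_ms,
         t0_ms = test_raster$t0_ms + warmup * test_raster$bin_ms),
    class = "firing_prob"
  )
}

#' @export
print.firing_prob <- function(x, ...) {
  cat(sprintf(
    "<firing_prob> %d bins x %d neurons (warm-up %d bins), mean pi = %.4g\n",
    nrow(x$pi), ncol(x$pi), x$offset, mean(x$pi)))
  invisible(x)
}

#' Threshold firing probabilities into a generated raster
#'
#' A neuron is regarded as firing at a bin when its predicted probability
#' strictly exceeds the threshold `h`. Monotone in `h`: raising the
#' threshold can only remove spikes.
#'
#' @param prob a [predict_probabilities()] result.
#' @param h threshold in (0, 1).
#' @return a generated [spike_raster()] aligned with the predicted bins.
#' @export
threshold_generate <- function(prob, h) {
  stopifnot(inherits(prob, "firing_prob"))
  if (h <= 0 || h >= 1) abort("`h` must lie strictly between 0 and 1.")
  X <- matrix(as.integer(prob$pi > h), nrow = nrow(prob$pi))
  spike_raster(X, neurons = prob$neurons, bin_ms = prob$bin_ms,
               t0_ms = prob$t0_ms)
}

#' Calibrate the generation threshold against a reference spike count
#'
#' Picks `h` so that the number of probability entries strictly above `h`
#' matches the reference raster's total spike count as closely as possible.
#' When the probability matrix covers a different number of bins than the
#' reference, the target count is scaled by the bin ratio so firing *rates*
#' are matched. The reference is normally the training raster: no canonical
#' threshold value exists for this kind of generation, so `h` is tied to a
#' quantity the model has already seen.
#'
#' @param prob a [predict_probabilities()] result.
#' @param reference either a [spike_raster()] or an [train_lstm()] model
#'   (whose stored training spike count is then used).
#' @return the threshold `h`.
#' @export
calibrate_threshold <- function(prob, reference) {
  stopifnot(inherits(prob, "firing_prob"))
  if (inherits(reference, "lstm_model")) {
    total <- reference$train_spikes
    ref_bins <- reference$train_bins
  } else if (inherits(reference, "spike_raster")) {
    total <- sum(reference$X)
    ref_bins <- n_bins(reference)
  } else {
    abort("`reference` must be a spike_raster or an lstm_model.")
  }
  v <- sort(as.numeric(prob$pi), decreasing = TRUE)
  if (max(v) - min(v) < 1e-12) {
    warn("all predicted probabilities are equal; returning h = 0.5.")
    return(0.5)
  }
  k <- round(total * nrow(prob$pi) / ref_bins)
  k <- max(0L, min(length(v), as.integer(k)))
  if (k == 0L) return(max(v))
  if (k >= length(v)) return(min(v) / 2)
  (v[k] + v[k + 1]) / 2
}
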