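test_that("focal loss reduces to cross-entropy at gamma 0 and matches hand values", {
  # single-element value: X = 1, pi = 0.5, gamma = 2 -> 0.25 * ln 2
  expect_equal(focal_loss(0.5, 1, gamma = 2), 0.25 * log(2), tolerance = 1e-12)

  set.seed(1)
  for (k in 1:100) {
    n <- sample(5:50, 1)
    pi <- runif(n, 0.01, 0.99)
    X <- rbinom(n, 1, 0.3)
    ce <- -sum(X * log(pi) + (1 - X) * log(1 - pi))
    expect_equal(focal_loss(pi, X, gamma = 0), ce, tolerance = 1e-10)
  }

  # perfect prediction limit: loss collapses towards zero
  X <- rbinom(200, 1, 0.2)
  pi <- pmin(pmax(X, 1e-7), 1 - 1e-7)
  expect_lt(focal_loss(pi, X, gamma = 2), 200 * 1e-7 * abs(log(1e-7)) + 1e-9)

  expect_error(focal_loss(c(0.1, 0.2), 1, gamma = 2), "shape mismatch")
  expect_error(focal_loss(0.5, 1, gamma = -1), ">= 0")
})

test_that("analytic BPTT gradients match finite differences", {
  set.seed(9)
  n <- 5; Tt <- 60; wl <- 20
  X <- matrix(rbinom(Tt * n, 1, 0.15), Tt, n) * 1.0
  cfg <- lstm_config(n, n_hidden_layers = 2, hidden_units = 4, epochs = 1,
                     window_len = wl, seed = 1)
  params <- spikegen:::init_lstm_params(cfg, base_rate = colMeans(X))
  starts <- c(0L, 13L)
  g <- spikegen:::lstm_grad_core(params, X, starts, wl, 2)
  fd <- function(setter) {
    eps <- 1e-6
    p1 <- setter(params, +eps); p2 <- setter(params, -eps)
    (spikegen:::lstm_loss_core(p1, X, starts, wl, 2) -
       spikegen:::lstm_loss_core(p2, X, starts, wl, 2)) / (2 * eps)
  }
  cases <- list(
    list(g$grads$V[2, 3],
         function(p, e) { p$V[2, 3] <- p$V[2, 3] + e; p }),
    list(g$grads$c[1],
         function(p, e) { p$c[1] <- p$c[1] + e; p }),
    list(g$grads$layers[[1]]$W[1, 2],
         function(p, e) { p$layers[[1]]$W[1, 2] <- p$layers[[1]]$W[1, 2] + e; p }),
    list(g$grads$layers[[1]]$U[2, 7],
         function(p, e) { p$layers[[1]]$U[2, 7] <- p$layers[[1]]$U[2, 7] + e; p }),
    list(g$grads$layers[[2]]$W[3, 9],
         function(p, e) { p$layers[[2]]$W[3, 9] <- p$layers[[2]]$W[3, 9] + e; p }),
    list(g$grads$layers[[2]]$b[14],
         function(p, e) { p$layers[[2]]$b[14] <- p$layers[[2]]$b[14] + e; p })
  )
  for (cs in cases) {
    num <- fd(cs[[2]])
    expect_equal(cs[[1]], num, tolerance = 1e-3)
  }
})

test_that("training reduces the loss on coupled synthetic data and is reproducible", {
  base <- rep(0.01, 8)
  W <- matrix(0, 8, 8); W[1, 2] <- 0.3; W[3, 4] <- 0.3
  r <- simulate_raster(coupling_from_matrix(base, W), duration_min = 0.5,
                       seed = 11)  # 30k bins
  cfg <- lstm_config(8, n_hidden_layers = 2, hidden_units = 8, epochs = 6,
                     window_len = 128, stride = 128, batch_size = 32,
                     lr = 3e-3, seed = 13)
  m1 <- train_lstm(r, cfg)
  expect_lt(tail(m1$trace$train_loss, 1), m1$trace$train_loss[1])
  expect_true(all(is.finite(m1$trace$train_loss)))
  expect_true(all(is.finite(m1$trace$val_loss)))
  expect_equal(nrow(m1$trace), 6L)

  m2 <- train_lstm(r, cfg)
  expect_equal(m1$trace, m2$trace)
  expect_equal(m1$params$V, m2$params$V)
})

test_that("an all-zero raster drives predictions and loss to zero", {
  r <- raster_from_spikes(3000, 6)
  cfg <- lstm_config(6, n_hidden_layers = 1, hidden_units = 4, epochs = 2,
                     window_len = 64, batch_size = 16, lr = 1e-2, seed = 2)
  m <- train_lstm(r, cfg)
  expect_lt(tail(m$trace$train_loss, 1), 1e-4)
  prob <- predict_probabilities(m, crop_raster(r, 1, 500))
  expect_lt(max(prob$pi), 0.01)
})

test_that("teacher-forced probabilities rise after a deterministic driver fires", {
  base <- c(0.05, 0.001, 0.01, 0.01)
  W <- matrix(0, 4, 4); W[1, 2] <- 0.9
  r <- simulate_raster(coupling_from_matrix(base, W), duration_min = 1,
                       seed = 21)
  train <- crop_raster(r, 1, 40000)
  test <- crop_raster(r, 40001, 60000)
  cfg <- lstm_config(4, n_hidden_layers = 2, hidden_units = 8, epochs = 12,
                     window_len = 128, stride = 32, batch_size = 64,
                     lr = 1e-2, seed = 22)
  m <- train_lstm(train, cfg)
  prob <- predict_probabilities(m, test)
  Xt <- test$X[(prob$offset + 1):n_bins(test), ]
  after <- which(Xt[-nrow(Xt), 1] == 1L) + 1L
  expect_gt(mean(prob$pi[after, 2]), 2 * mean(prob$pi[-after, 2]))
})

test_that("prediction respects the warm-up contract and boundaries", {
  r <- random_raster(600, 5, p = 0.05, seed = 31)
  cfg <- lstm_config(5, n_hidden_layers = 1, hidden_units = 4, epochs = 1,
                     window_len = 100, batch_size = 4, seed = 3)
  m <- train_lstm(r, cfg)
  # exactly window_len + 1 bins -> one predictable row
  p1 <- predict_probabilities(m, crop_raster(r, 1, 101))
  expect_equal(nrow(p1$pi), 1L)
  expect_error(predict_probabilities(m, crop_raster(r, 1, 100)), "too short")
  p <- predict_probabilities(m, r)
  expect_equal(nrow(p$pi), 600L - 100L)
  expect_true(all(p$pi > 0 & p$pi < 1))
})

test_that("thresholding is strict, monotone and respects limits", {
  pi <- matrix(c(0.7, 0.2, 0.9, 0.05), 2, 2)
  prob <- structure(list(pi = pi, offset = 0L, neurons = neuron_meta(0:1),
                         bin_ms = 1, t0_ms = 0), class = "firing_prob")
  g <- threshold_generate(prob, 0.7)
  expect_equal(g$X[1, 1], 0L)  # pi == h stays silent (strict inequality)
  expect_equal(g$X[1, 2], 1L)
  expect_equal(sum(threshold_generate(prob, 1 - 1e-9)$X), 0L)
  expect_equal(sum(threshold_generate(prob, 1e-9)$X), 4L)
  # monotone: spikes at a higher threshold are a subset
  g_lo <- threshold_generate(prob, 0.1)
  g_hi <- threshold_generate(prob, 0.5)
  expect_true(all(g_lo$X >= g_hi$X))
})

test_that("threshold calibration matches the reference count", {
  set.seed(17)
  pi <- matrix(runif(10000), 1000, 10)
  prob <- structure(list(pi = pi, offset = 0L, neurons = neuron_meta(0:9),
                         bin_ms = 1, t0_ms = 0), class = "firing_prob")
  target <- raster_from_spikes(1000, 10)
  target$X[seq_len(1000), ] <- matrix(rbinom(10000, 1, 0.1), 1000, 10)
  h <- calibrate_threshold(prob, target)
  expect_equal(h, 0.9, tolerance = 0.02)  # 10% of uniform mass above h
  expect_equal(sum(pi > h), sum(target$X), tolerance = 2)

  zero <- raster_from_spikes(1000, 10)
  expect_gte(calibrate_threshold(prob, zero), max(pi))
  ones <- raster_from_spikes(1000, 10)
  ones$X[] <- 1L
  expect_lt(calibrate_threshold(prob, ones), min(pi))

  flat <- structure(list(pi = matrix(0.3, 10, 2), offset = 0L,
                         neurons = neuron_meta(0:1), bin_ms = 1, t0_ms = 0),
                    class = "firing_prob")
  expect_warning(h_flat <- calibrate_threshold(flat, zero), "equal")
  expect_equal(h_flat, 0.5)
})

test_that("configuration contracts are validated", {
  expect_error(lstm_config(8, epochs = 0), "epochs")
  expect_error(lstm_config(8, window_len = 1), "window_len")
  expect_error(lstm_config(8, threshold_h = 1.2), "between 0 and 1")
  r <- random_raster(500, 4, seed = 5)
  cfg <- lstm_config(8, n_hidden_layers = 1, hidden_units = 4, epochs = 1,
                     window_len = 64)
  expect_error(train_lstm(r, cfg), "neurons")
})
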