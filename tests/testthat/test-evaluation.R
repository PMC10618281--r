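test_that("firing rates are spikes per second", {
  r <- raster_from_spikes(60000, 2)      # 60 s at 1-ms bins
  r$X[seq_len(120), 1] <- 1L             # 120 spikes in 60 s
  fr <- firing_rate(r)
  expect_equal(fr$rate, c(2, 0))

  ones <- raster_from_spikes(1000, 1)
  ones$X[] <- 1L
  expect_equal(firing_rate(ones)$rate, 1000)  # bin-rate ceiling at 1 ms
})

test_that("rate correlations handle identity, reflection and the null", {
  meta <- neuron_meta(0:127, ei_type = rep(c("inhibitory", "excitatory"),
                                           c(32, 96)))
  fr <- function(rate) tibble::tibble(neuron_id = 0:127,
                                      ei_type = meta$ei_type,
                                      layer = 1L, n_spikes = 0L, rate = rate)
  set.seed(5)
  x <- runif(128, 0, 10)
  expect_equal(rate_correlation(fr(x), fr(x))$r, 1)
  expect_equal(rate_correlation(fr(x), fr(-x + 3))$r, -1)
  y <- runif(128, 0, 10)  # independent vectors stay near zero
  expect_lt(abs(rate_correlation(fr(x), fr(y))$r), 0.3)

  flat <- rate_correlation(fr(x), fr(rep(2, 128)))
  expect_false(flat$defined)
  expect_true(is.na(flat$r))
  tiny <- rate_correlation(fr(x)[1:2, ], fr(y)[1:2, ])
  expect_false(tiny$defined)
})

test_that("the independence null probability follows 1 - (1 - p)^D", {
  expect_equal(sync_null_prob(0.1, 1), 0.1)
  expect_equal(sync_null_prob(0, 5), 0)
  expect_equal(sync_null_prob(0.1, 3), 1 - 0.9^3)
  # strict monotonicity in D and p on a grid
  p <- seq(0.05, 0.95, by = 0.05)
  for (D in 1:4) {
    expect_true(all(sync_null_prob(p, D + 1) > sync_null_prob(p, D)))
  }
  expect_true(all(diff(sync_null_prob(p, 3)) > 0))
  expect_error(sync_null_prob(0.1, 0), ">= 1")
})

test_that("sync_score reproduces the worked three-spike example", {
  r <- raster_from_spikes(100, 2,
                          data.frame(bin = c(11, 21, 31, 12, 22, 32),
                                     neuron = rep(1:2, each = 3)))
  zs <- sync_score(r, D = 1)
  expect_equal(zs$N, c(3, 3))
  expect_equal(zs$p[2], 0.03)
  expect_equal(zs$C[1, 2], 3)
  expect_equal(zs$Z[1, 2], (3 - 3 * 0.03) / sqrt(3 * 0.03 * 0.97),
               tolerance = 1e-12)
  # against the brute-force oracle too
  bf <- sync_score_bruteforce(r, 1)
  expect_equal(zs$C, bf$C)
  expect_equal(zs$Z[1, 2], bf$Z[1, 2], tolerance = 1e-12)
})

test_that("vectorized sync_score equals the nested-loop oracle exactly", {
  set.seed(404)
  for (k in 1:20) {
    n <- sample(3:8, 1)
    Tn <- sample(200:800, 1)
    D <- sample(1:3, 1)
    r <- random_raster(Tn, n, p = runif(1, 0.01, 0.08))
    zs <- sync_score(r, D = D)
    bf <- sync_score_bruteforce(r, D)
    expect_equal(unname(zs$C), bf$C)
    expect_equal(unname(zs$N), as.numeric(bf$N))
    expect_equal(unname(zs$q_bar), bf$q)
    expect_equal(unname(zs$Z), bf$Z, tolerance = 1e-12)
  }
})

test_that("silent sources and degenerate nulls are flagged undefined", {
  r <- raster_from_spikes(50, 3, data.frame(bin = c(5, 6), neuron = c(2, 3)))
  zs <- sync_score(r, D = 1)
  expect_false(any(zs$defined[1, ]))   # neuron 1 never fires
  expect_true(all(is.na(zs$Z[1, ])))
  expect_false(any(diag(zs$defined)))
  ones <- raster_from_spikes(50, 2)
  ones$X[, 1] <- 1L
  ones$X[25, 2] <- 1L
  zs2 <- sync_score(ones, D = 1)
  expect_false(zs2$defined[2, 1])      # q_bar = 1 for the always-firing target
})

test_that("the no-sqrt compatibility flag divides by the variance instead", {
  r <- random_raster(500, 4, p = 0.05, seed = 12)
  a <- sync_score(r, D = 1, sqrt_denominator = TRUE)
  b <- sync_score(r, D = 1, sqrt_denominator = FALSE)
  sd_mat <- sqrt(outer(a$N, a$q_bar * (1 - a$q_bar)))
  expect_equal(a$Z * sd_mat, b$Z * sd_mat^2, tolerance = 1e-12)
})

test_that("polar quadrants capture the diagonal and axis cases", {
  mk_sync <- function(Z) {
    n <- nrow(Z)
    defined <- !diag(n) & is.finite(Z)
    structure(list(Z = ifelse(defined, Z, NA_real_), defined = defined,
                   N = rep(1, n), p = rep(0.1, n), q_bar = rep(0.1, n),
                   D = 1L, neurons = neuron_meta(seq_len(n) - 1L)),
              class = "sync_score")
  }
  set.seed(2)
  Zr <- matrix(runif(25, 1, 5), 5, 5)
  # identical positive scores -> every point at exactly pi/4
  q1 <- polar_quadrant(mk_sync(Zr), mk_sync(Zr), "Q1")
  expect_true(all(abs(q1$points$theta - pi / 4) < 1e-12))
  expect_equal(sum(q1$histogram$count > 0), 1L)

  # identical negative scores -> all theta = 5 pi / 4 in Q3
  q3 <- polar_quadrant(mk_sync(-Zr), mk_sync(-Zr), "Q3")
  expect_true(all(abs(q3$points$theta - 5 * pi / 4) < 1e-12))

  # generated scores collapsing to zero from above -> theta near 0, off-peak
  q0 <- polar_quadrant(mk_sync(Zr), mk_sync(Zr * 1e-9), "Q1")
  expect_true(all(q0$points$theta < 0.01))

  empty <- suppressWarnings(polar_quadrant(mk_sync(Zr), mk_sync(Zr), "Q3"))
  expect_true(empty$empty)
})

test_that("detrending removes exactly the fitted slope and keeps the mean", {
  mk_hist <- function(counts) {
    nb <- length(counts)
    bw <- (pi / 2) / nb
    structure(list(points = tibble::tibble(),
                   histogram = tibble::tibble(
                     bin_mid = bw * (seq_len(nb) - 0.5), count = counts),
                   quadrant = "Q1", lo = 0, hi = pi / 2, bin_width = bw,
                   detrended = FALSE, empty = FALSE),
              class = "polar_quadrant")
  }
  flat <- mk_hist(rep(4, 45))
  expect_equal(detrend_histogram(flat)$histogram$count, rep(4, 45))

  lin <- mk_hist(seq(1, 45))
  det <- detrend_histogram(lin)
  expect_equal(det$histogram$count, rep(mean(1:45), 45), tolerance = 1e-9)

  set.seed(3)
  noisy <- mk_hist(runif(45, 0, 10))
  expect_equal(mean(detrend_histogram(noisy)$histogram$count),
               mean(noisy$histogram$count), tolerance = 1e-12)
})

test_that("sharpness baselines: uniform histogram scores one, spikes explode", {
  mk_hist <- function(counts, lo = 0) {
    nb <- length(counts)
    bw <- (pi / 2) / nb
    structure(list(points = tibble::tibble(),
                   histogram = tibble::tibble(
                     bin_mid = lo + bw * (seq_len(nb) - 0.5), count = counts),
                   quadrant = if (lo == 0) "Q1" else "Q3", lo = lo,
                   hi = lo + pi / 2, bin_width = bw, detrended = TRUE,
                   empty = FALSE),
              class = "polar_quadrant")
  }
  uni <- sharpness(mk_hist(rep(7, 45)))
  expect_equal(uni$sharpness, 1, tolerance = 0.02)

  # invariance to positive scaling of the counts
  expect_equal(sharpness(mk_hist(rep(7, 45) * 13))$sharpness, uni$sharpness)

  # all mass in one central bin -> infinite with a warning
  spike <- rep(0, 45); spike[23] <- 10
  expect_warning(res <- sharpness(mk_hist(spike)), "Inf")
  expect_true(is.infinite(res$sharpness))

  # two equal bins, one inside the window, one outside -> ratio 1
  two <- rep(0, 45); two[23] <- 5; two[2] <- 5
  expect_equal(sharpness(mk_hist(two))$sharpness, 1, tolerance = 1e-9)
})

test_that("evaluating a raster against itself is the upper bound", {
  pop <- make_population(24, 0.25, c(2, 10), seed = 31)
  cm <- make_coupling(pop, n_excitatory = 30, strength = 0.05, seed = 32)
  r <- simulate_raster(cm, 1, seed = 33)
  ev <- evaluate_pair(r, r)
  expect_equal(ev$rate_cor$r[ev$rate_cor$subset == "all"], 1)
  sq1 <- ev$sharpness$sharpness[ev$sharpness$quadrant == "Q1"]
  expect_gt(sq1, 20 * 1)  # identity scatter hugs pi/4 far above uniform

  # time-shuffled generation destroys sync structure: sharpness near baseline
  set.seed(34)
  shuf <- r
  shuf$X <- r$X[sample.int(nrow(r$X)), ]
  ev_s <- evaluate_pair(r, shuf)
  sq1_s <- ev_s$sharpness$sharpness[ev_s$sharpness$quadrant == "Q1"]
  expect_lt(sq1_s, sq1 / 4)
  expect_equal(ev_s$rate_cor$r[1], 1)  # rates survive shuffling

  zero <- raster_from_spikes(n_bins(r), 24, neurons = r$neurons)
  ev_z <- evaluate_pair(r, zero)
  expect_false(any(ev_z$rate_cor$defined))
})

test_that("planted couplings separate from the uncoupled background", {
  pop <- make_population(20, 0.2, c(2, 8), seed = 41)
  cm <- make_coupling(pop, n_excitatory = 12, strength = 0.05, seed = 42)
  r <- simulate_raster(cm, 3, seed = 43)
  zs <- sync_score(r, D = 1)
  mask <- matrix(FALSE, 20, 20)
  mask[cbind(cm$couplings$source, cm$couplings$target)] <- TRUE
  zc <- zs$Z[mask]
  zu <- zs$Z[zs$defined & !mask]
  expect_true(all(zc > quantile(zu, 0.99)))
})

test_that("an inhibitory coupling yields a negative synchronization score", {
  base <- c(0.02, 0.02)
  W <- matrix(0, 2, 2); W[1, 2] <- -0.02
  r <- suppressMessages(
    simulate_raster(coupling_from_matrix(base, W), 3, seed = 44))
  zs <- sync_score(r, D = 1)
  expect_lt(zs$Z[1, 2], -3)
  expect_gt(zs$Z[1, 2], -50)
})
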