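# Shared fixtures and independent oracles used across the suite.

# Small raster from explicit spike coordinates (1-based bins).
raster_from_spikes <- function(n_bins, n_neurons, spikes = NULL,
                               neurons = NULL, bin_ms = 1) {
  X <- matrix(0L, n_bins, n_neurons)
  if (!is.null(spikes) && nrow(spikes) > 0) {
    X[cbind(spikes$bin, spikes$neuron)] <- 1L
  }
  spike_raster(X, neurons = neurons, bin_ms = bin_ms)
}

random_raster <- function(n_bins, n_neurons, p = 0.05, seed = NULL,
                          neurons = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rbinom(n_bins * n_neurons, 1L, p), n_bins, n_neurons)
  spike_raster(X, neurons = neurons)
}

# Literal nested-loop implementation of the synchronization-score counts:
# for every source spike, open a window of D bins strictly after it and
# count windows containing at least one target spike.
sync_score_bruteforce <- function(raster, D) {
  X <- raster$X
  Tn <- nrow(X)
  n <- ncol(X)
  N <- integer(n)
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ts <- which(X[, i] == 1L)
    N[i] <- length(ts)
    for (j in seq_len(n)) {
      cnt <- 0L
      for (t in ts) {
        hi <- min(Tn, t + D)
        if (t + 1 <= hi && any(X[(t + 1):hi, j] == 1L)) cnt <- cnt + 1L
      }
      C[i, j] <- cnt
    }
  }
  p <- N / Tn
  q <- 1 - (1 - p)^D
  Z <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && N[i] > 0 && q[j] > 0 && q[j] < 1) {
        Z[i, j] <- (C[i, j] - N[i] * q[j]) / sqrt(N[i] * q[j] * (1 - q[j]))
      }
    }
  }
  list(C = C, N = N, q = q, Z = Z)
}

# Exact two-sided Mann-Whitney p value by exhaustive enumeration of all
# assignments of ranks to the first group (no ties assumed).
mann_whitney_exact <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Coupling model wrapper for hand-built W matrices.
coupling_from_matrix <- function(base, W, delay = 1L, neurons = NULL) {
  n <- length(base)
  if (is.null(neurons)) neurons <- neuron_meta(seq_len(n) - 1L)
  structure(list(base_prob = base, W = W, delay = as.integer(delay),
                 neurons = neurons, couplings = NULL),
            class = "coupling_model")
}
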