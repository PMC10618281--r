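# Synthetic rasters with known excitatory/inhibitory coupling structure, and
# toy atlas fixtures. These stand in for slice recordings so that every
# downstream stage (training, generation, evaluation, anatomy, statistics)
# can be exercised and validated against known ground truth.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialise a seed to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Create a synthetic neural population
#'
#' Draws per-neuron baseline firing rates log-uniformly in `rate_range`
#' (spikes/s) and converts them to per-bin firing probabilities
#' `p = rate * bin_ms / 1000`. The first `round(n * frac_inh)` neurons are
#' inhibitory; layers are assigned round-robin from 6 down to 1 within each
#' class, matching the canonical raster ordering.
#'
#' @param n number of neurons.
#' @param frac_inh fraction of inhibitory neurons in `[0, 1]` (default 0.2).
#' @param rate_range numeric length-2, baseline firing-rate range in
#'   spikes/s (default `c(1, 10)`).
#' @param bin_ms bin width the probabilities refer to (default 1 ms).
#' @param seed optional RNG seed (the global RNG state is restored).
#' @return list with `neurons` (a [neuron_meta()] tibble) and `base_prob`
#'   (per-bin baseline firing probabilities).
#' @export
make_population <- function(n, frac_inh = 0.2, rate_range = c(1, 10),
                            bin_ms = 1, seed = NULL) {
  if (n < 1) abort("`n` must be at least 1.")
  if (frac_inh < 0 || frac_inh > 1) abort("`frac_inh` must be in [0, 1].")
  if (any(rate_range <= 0) || rate_range[2] < rate_range[1]) {
    abort("`rate_range` must be a positive increasing interval.")
  }
  with_seed(seed, {
    rates <- exp(runif(n, log(rate_range[1]), log(rate_range[2])))
    n_inh <- as.integer(round(n * frac_inh))
    ei <- c(rep("inhibitory", n_inh), rep("excitatory", n - n_inh))
    layer_cycle <- rep_len(6:1, n)
    layers <- c(head(rep_len(6:1, n_inh), n_inh),
                rep_len(6:1, n - n_inh))
    neurons <- neuron_meta(seq_len(n) - 1L, ei_type = ei, layer = layers)
    list(neurons = neurons, base_prob = rates * bin_ms / 1000)
  })
}

#' Coupling model for the raster simulator
#'
#' Builds a signed coupling matrix `W` (source row, target column): a spike
#' of neuron `i` at bin `t` adds `W[i, j]` to neuron `j`'s firing probability
#' at bin `t + delay`. Couplings from excitatory sources are non-negative,
#' couplings from inhibitory sources non-positive. Coupled ordered pairs are
#' sampled uniformly without replacement among pairs with the required
#' source class (self-couplings excluded).
#'
#' @param population output of [make_population()].
#' @param n_excitatory number of excitatory couplings (default 40).
#' @param n_inhibitory number of inhibitory couplings (default 0).
#' @param strength probability increment of an excitatory coupling
#'   (default 0.03).
#' @param inh_strength probability decrement magnitude of an inhibitory
#'   coupling (default `strength`).
#' @param delay coupling delay in bins (default 1, matching the 1 ms
#'   acceptable delay of the synchronization score).
#' @param seed optional RNG seed.
#' @return list of class `coupling_model` with `base_prob`, `W`, `delay`,
#'   `neurons` and a tibble `couplings` of the planted pairs.
#' @export
make_coupling <- function(population, n_excitatory = 40, n_inhibitory = 0,
                          strength = 0.03, inh_strength = strength,
                          delay = 1L, seed = NULL) {
  neurons <- population$neurons
  n <- nrow(neurons)
  if (delay < 1) abort("`delay` must be >= 1 bin.")
  with_seed(seed, {
    W <- matrix(0, n, n)
    pick_pairs <- function(sources, k) {
      pairs <- expand.grid(source = sources, target = seq_len(n))
      pairs <- pairs[pairs$source != pairs$target, ]
      if (k > nrow(pairs)) abort("more couplings requested than pairs exist.")
      pairs[sample.int(nrow(pairs), k), ]
    }
    exc <- which(neurons$ei_type == "excitatory")
    inh <- which(neurons$ei_type == "inhibitory")
    planted <- list()
    if (n_excitatory > 0) {
      if (length(exc) == 0) abort("no excitatory neurons to source couplings.")
      pe <- pick_pairs(exc, n_excitatory)
      W[cbind(pe$source, pe$target)] <- strength
      planted$exc <- tibble(source = pe$source, target = pe$target,
                            weight = strength)
    }
    if (n_inhibitory > 0) {
      if (length(inh) == 0) abort("no inhibitory neurons to source couplings.")
      pi_ <- pick_pairs(inh, n_inhibitory)
      W[cbind(pi_$source, pi_$target)] <- -inh_strength
      planted$inh <- tibble(source = pi_$source, target = pi_$target,
                            weight = -inh_strength)
    }
    structure(
      list(base_prob = population$base_prob, W = W, delay = as.integer(delay),
           neurons = neurons,
           couplings = bind_rows(planted)),
      class = "coupling_model"
    )
  })
}

#' Simulate a coupled-Bernoulli spike raster
#'
#' Each neuron fires independently per bin with probability
#' `clip(base_j + sum_i W[i, j] * X[t - delay, i], 0, 1)`. With `W = 0` all
#' neurons are independent Bernoulli processes at their baseline rates. The
#' additive-probability coupling makes conditional rates analytically
#' predictable, which the evaluation tests exploit. Probabilities escaping
#' `[0, 1]` are clipped and counted (reported via a message), not fatal.
#'
#' @param model a [make_coupling()] model (or a list with `base_prob`, `W`,
#'   `delay`, `neurons`).
#' @param duration_min raster duration in minutes.
#' @param bin_ms bin width in ms (default 1).
#' @param seed optional RNG seed.
#' @param region optional [region_label()] attached to the raster.
#' @return a [spike_raster()].
#' @export
simulate_raster <- function(model, duration_min, bin_ms = 1, seed = NULL,
                            region = NULL) {
  if (duration_min <= 0) abort("`duration_min` must be positive.")
  n_bins <- as.integer(round(duration_min * 60000 / bin_ms))
  with_seed(seed, {
    res <- sim_coupled_core(model$base_prob, model$W, n_bins, model$delay)
    if (res$clipped > 0) {
      inform(sprintf("simulate_raster: clipped %d probabilities to [0, 1].",
                     res$clipped))
    }
    spike_raster(res$X, neurons = model$neurons, bin_ms = bin_ms,
                 region = region)
  })
}

#' Toy atlas fixture
#'
#' Builds an atlas whose cortical areas are axis-aligned rectangles
#' partitioning a square world (a grid with randomly jittered internal cut
#' lines), a non-negative inter-area connection weight matrix, and a set of
#' square recording windows with region labels. Rectangle geometry keeps all
#' window/area intersection areas exactly computable.
#'
#' @param n_side number of grid cells per axis (default 4; areas =
#'   `n_side^2`).
#' @param world_size side length of the square world (default 100).
#' @param n_windows number of recording windows (default 2).
#' @param window_size side length of each square window (default
#'   `world_size / 4`).
#' @param weight_range range of the positive entries of the weight matrix.
#' @param weight_density fraction of area pairs with a nonzero weight.
#' @param seed optional RNG seed.
#' @return list of class `atlas_fixture` with tibbles `areas` (area_id and
#'   rectangle bounds) and `windows` (window_id, bounds, hemisphere,
#'   angular_group, dataset_id), and matrix `W` (named by area_id).
#' @export
make_atlas_fixture <- function(n_side = 4, world_size = 100, n_windows = 2,
                               window_size = world_size / 4,
                               weight_range = c(1, 10), weight_density = 0.5,
                               seed = NULL) {
  if (n_side < 1) abort("`n_side` must be >= 1.")
  with_seed(seed, {
    jitter_cuts <- function() {
      inner <- sort(runif(n_side - 1, 0.25, 0.75) +
                      seq_len(n_side - 1) - 1) * world_size / n_side
      c(0, inner, world_size)
    }
    xs <- jitter_cuts()
    ys <- jitter_cuts()
    grid <- expand.grid(ix = seq_len(n_side), iy = seq_len(n_side))
    areas <- tibble(
      area_id = sprintf("A%02d", seq_len(nrow(grid))),
      xmin = xs[grid$ix], xmax = xs[grid$ix + 1],
      ymin = ys[grid$iy], ymax = ys[grid$iy + 1]
    )
    areas$area <- (areas$xmax - areas$xmin) * (areas$ymax - areas$ymin)
    n_a <- nrow(areas)
    W <- matrix(0, n_a, n_a, dimnames = list(areas$area_id, areas$area_id))
    nz <- runif(n_a * n_a) < weight_density
    W[nz] <- runif(sum(nz), weight_range[1], weight_range[2])
    diag(W) <- 0
    groups <- angular_groups()
    wx <- runif(n_windows, 0, world_size - window_size)
    wy <- runif(n_windows, 0, world_size - window_size)
    windows <- tibble(
      window_id = sprintf("W%02d", seq_len(n_windows)),
      xmin = wx, xmax = wx + window_size,
      ymin = wy, ymax = wy + window_size,
      hemisphere = rep_len(c("L", "R"), n_windows),
      angular_group = rep_len(groups, n_windows),
      dataset_id = rep_len(1:2, n_windows)
    )
    structure(list(areas = areas, windows = windows, W = W),
              class = "atlas_fixture")
  })
}

#' Write or read an atlas fixture as JSON
#'
#' @param atlas an [make_atlas_fixture()] object.
#' @param path JSON file path.
#' @return `read_atlas()` returns an `atlas_fixture`; `write_atlas()` the
#'   path, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  payload <- list(
    areas = atlas$areas,
    windows = atlas$windows,
    W = list(area_ids = rownames(atlas$W), values = unname(atlas$W))
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- as.matrix(payload$W$values)
  dimnames(W) <- list(payload$W$area_ids, payload$W$area_ids)
  structure(list(areas = as_tibble(payload$areas),
                 windows = as_tibble(payload$windows), W = W),
            class = "atlas_fixture")
}
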