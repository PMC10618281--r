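#' Binary spike raster
#'
#' A spike raster is a binary matrix `X` with one row per time bin and one
#' column per neuron: `X[t, i] = 1` if neuron `i` fired at least once in bin
#' `t`. Bins are half-open intervals `[t0 + (t-1) * bin_ms, t0 + t * bin_ms)`
#' with 1 ms the conventional width. Per-neuron metadata (excitatory or
#' inhibitory class, cortical layer 1-6) travels with the matrix as a tibble,
#' together with an optional region label identifying which of the 16
#' hemisphere-by-angle cortical groups the population was recorded from.
#'
#' @param X binary matrix (integer or numeric 0/1), rows = time bins,
#'   columns = neurons.
#' @param neurons tibble with one row per column of `X`, columns
#'   `neuron_id` (unique integers), `ei_type` (`"inhibitory"` or
#'   `"excitatory"`) and `layer` (integer 1-6). Created with
#'   [neuron_meta()] if omitted metadata is acceptable for the analysis.
#' @param bin_ms bin width in milliseconds (default 1).
#' @param t0_ms absolute start time of the first bin in milliseconds.
#' @param region optional [region_label()] for the whole population.
#'
#' @return An object of class `spike_raster`.
#' @seealso [neuron_meta()], [region_label()], [sort_neurons()],
#'   [segment_raster()], [read_raster()]
#' @export
spike_raster <- function(X, neurons = NULL, bin_ms = 1, t0_ms = 0,
                         region = NULL) {
  if (!is.matrix(X)) abort("`X` must be a matrix of 0/1 spike indicators.")
  storage.mode(X) <- "integer"
  bad <- !(X %in% c(0L, 1L))
  if (any(bad)) abort("`X` must contain only 0 and 1.")
  if (is.null(neurons)) {
    neurons <- neuron_meta(seq_len(ncol(X)) - 1L)
  }
  neurons <- validate_neuron_meta(neurons, n = ncol(X))
  if (!is.numeric(bin_ms) || length(bin_ms) != 1L || bin_ms <= 0) {
    abort("`bin_ms` must be a single positive number.")
  }
  if (!is.null(region)) region <- validate_region_label(region)
  structure(
    list(X = X, neurons = neurons, bin_ms = as.numeric(bin_ms),
         t0_ms = as.numeric(t0_ms), region = region),
    class = "spike_raster"
  )
}

#' Neuron metadata tibble
#'
#' @param neuron_id integer ids, unique within a raster.
#' @param ei_type `"inhibitory"` or `"excitatory"`, recycled.
#' @param layer cortical layer 1-6, recycled.
#' @return tibble with columns `neuron_id`, `ei_type`, `layer`.
#' @export
neuron_meta <- function(neuron_id, ei_type = "excitatory", layer = 1L) {
  tibble(
    neuron_id = as.integer(neuron_id),
    ei_type = rep_len(as.character(ei_type), length(neuron_id)),
    layer = rep_len(as.integer(layer), length(neuron_id))
  )
}

validate_neuron_meta <- function(neurons, n = NULL) {
  if (!is.data.frame(neurons)) abort("`neurons` must be a data frame.")
  neurons <- as_tibble(neurons)
  req <- c("neuron_id", "ei_type", "layer")
  miss <- setdiff(req, names(neurons))
  if (length(miss) > 0) {
    abort(paste0("neuron metadata is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (!is.null(n) && nrow(neurons) != n) {
    abort(sprintf("raster has %d neuron columns but metadata has %d rows.",
                  n, nrow(neurons)))
  }
  if (anyDuplicated(neurons$neuron_id) > 0) {
    abort("`neuron_id` must be unique within a raster.")
  }
  if (!all(neurons$ei_type %in% c("inhibitory", "excitatory"))) {
    abort("`ei_type` must be 'inhibitory' or 'excitatory'.")
  }
  if (anyNA(neurons$layer) || !all(neurons$layer %in% 1:6)) {
    abort("`layer` must be an integer in 1..6.")
  }
  neurons
}

#' The eight angular cortical groups
#'
#' Group names are built from the four compass-like anatomical directions
#' O (occipital), D (dorsal), F (frontal) and V (ventral); consecutive names
#' are 45 degrees apart around the axis joining the two ears, so position
#' `k` (0-7) sits at `k * 45` degrees. Two groups exist per hemisphere for
#' each of the 8 positions, giving the 16 region groups.
#'
#' @return character vector of the 8 group names in ring order.
#' @export
angular_groups <- function() {
  c("D", "DF", "F", "FV", "V", "VO", "O", "OD")
}

#' Region label
#'
#' Identifies one of the 16 cortical region groups (8 angular positions x 2
#' hemispheres) plus which of the two replicate datasets the recording
#' belongs to.
#'
#' @param hemisphere `"L"` or `"R"`.
#' @param angular_group one of [angular_groups()].
#' @param dataset_id 1 or 2.
#' @return list of class `region_label`.
#' @export
region_label <- function(hemisphere, angular_group, dataset_id = 1L) {
  validate_region_label(list(
    hemisphere = hemisphere,
    angular_group = angular_group,
    dataset_id = as.integer(dataset_id)
  ))
}

validate_region_label <- function(x) {
  if (inherits(x, "region_label")) return(x)
  if (!is.list(x)) abort("a region label must be a list or region_label.")
  if (!x$hemisphere %in% c("L", "R")) {
    abort("`hemisphere` must be 'L' or 'R'.")
  }
  if (!x$angular_group %in% angular_groups()) {
    abort(paste0("`angular_group` must be one of: ",
                 paste(angular_groups(), collapse = ", ")))
  }
  if (!x$dataset_id %in% c(1L, 2L)) abort("`dataset_id` must be 1 or 2.")
  structure(x[c("hemisphere", "angular_group", "dataset_id")],
            class = "region_label")
}

#' @export
format.region_label <- function(x, ...) {
  sprintf("%s-%s (dataset %d)", x$hemisphere, x$angular_group, x$dataset_id)
}

#' @export
print.region_label <- function(x, ...) {
  cat("<region_label>", format(x), "\n")
  invisible(x)
}

#' @export
print.spike_raster <- function(x, ...) {
  dur_s <- n_bins(x) * x$bin_ms / 1000
  cat(sprintf(
    "<spike_raster> %d neurons x %d bins (%.3g s at %g ms bins), %d spikes\n",
    n_neurons(x), n_bins(x), dur_s, x$bin_ms, sum(x$X)
  ))
  if (!is.null(x$region)) cat("  region:", format(x$region), "\n")
  tab <- table(x$neurons$ei_type)
  cat("  neurons:", paste(sprintf("%s %s", tab, names(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Raster dimensions and duration
#'
#' @param raster a [spike_raster()].
#' @return `n_bins()` and `n_neurons()` return integers; `duration_sec()`
#'   the raster duration in seconds.
#' @export
n_bins <- function(raster) nrow(raster$X)

#' @rdname n_bins
#' @export
n_neurons <- function(raster) ncol(raster$X)

#' @rdname n_bins
#' @export
duration_sec <- function(raster) nrow(raster$X) * raster$bin_ms / 1000

#' Crop a raster to a bin range
#'
#' Keeps bins `from..to` (1-based, inclusive) and shifts `t0_ms` accordingly.
#'
#' @param raster a [spike_raster()].
#' @param from,to 1-based bin indices; `to` defaults to the last bin.
#' @return a [spike_raster()].
#' @export
crop_raster <- function(raster, from = 1L, to = n_bins(raster)) {
  stopifnot(inherits(raster, "spike_raster"))
  if (from < 1L || to > n_bins(raster) || from > to) {
    abort("invalid bin range in `crop_raster()`.")
  }
  spike_raster(
    raster$X[from:to, , drop = FALSE],
    neurons = raster$neurons,
    bin_ms = raster$bin_ms,
    t0_ms = raster$t0_ms + (from - 1) * raster$bin_ms,
    region = raster$region
  )
}

#' Canonical neuron ordering
#'
#' Reorders raster columns so inhibitory neurons come before excitatory
#' neurons, and within each class neurons are sorted by cortical layer in
#' descending order (6 down to 1). The sort is stable: neurons tied on
#' (class, layer) keep their relative order. Applying the sort twice equals
#' applying it once.
#'
#' @param raster a [spike_raster()] whose metadata has `ei_type` and `layer`
#'   for every neuron.
#' @return a [spike_raster()] with permuted columns and metadata.
#' @export
sort_neurons <- function(raster) {
  stopifnot(inherits(raster, "spike_raster"))
  meta <- validate_neuron_meta(raster$neurons, n = n_neurons(raster))
  class_rank <- ifelse(meta$ei_type == "inhibitory", 0L, 1L)
  ord <- order(class_rank, -meta$layer)  # order() is stable
  spike_raster(
    raster$X[, ord, drop = FALSE],
    neurons = meta[ord, ],
    bin_ms = raster$bin_ms,
    t0_ms = raster$t0_ms,
    region = raster$region
  )
}

#' Cut the two analysis segments out of a recording
#'
#' After discarding an initial burn-in (firing is unstable early in a
#' recording), two equal-length segments are cut: the earlier segment starts
#' at `burn_in_min` and the later segment starts one (scaled) minute after
#' the earlier one ends, leaving a gap that keeps them temporally disjoint.
#' At the defaults (30 min burn-in, 17 min segments) the segments are
#' minutes 30-47 and 48-65. For scaled runs the 1-minute gap scales
#' proportionally with the segment length: `gap_min = seg_min / 17`.
#'
#' @param raster a [spike_raster()] covering at least
#'   `burn_in_min + 2 * seg_min + gap_min` minutes.
#' @param burn_in_min minutes discarded at the start (default 30).
#' @param seg_min segment length in minutes (default 17).
#' @return list with elements `earlier` and `later`, both [spike_raster()]s
#'   of exactly `seg_min * 60000 / bin_ms` bins.
#' @export
segment_raster <- function(raster, burn_in_min = 30, seg_min = 17) {
  stopifnot(inherits(raster, "spike_raster"))
  bin_ms <- raster$bin_ms
  bins_per_min <- 60000 / bin_ms
  gap_bins <- as.integer(round(bins_per_min * seg_min / 17))
  seg_bins <- as.integer(round(seg_min * bins_per_min))
  start1 <- as.integer(round(burn_in_min * bins_per_min))
  start2 <- start1 + seg_bins + gap_bins
  need <- start2 + seg_bins
  if (n_bins(raster) < need) {
    abort(sprintf(
      "raster too short: %d bins available but %d required (burn-in %g min + 2 x %g min segments + %g min gap).",
      n_bins(raster), need, burn_in_min, seg_min, seg_min / 17
    ))
  }
  list(
    earlier = crop_raster(raster, start1 + 1L, start1 + seg_bins),
    later = crop_raster(raster, start2 + 1L, start2 + seg_bins)
  )
}

#' Pair a training segment with a test segment
#'
#' In same-region mode the earlier segment of a region is the training data
#' and the later segment of the same region the test data. In cross-region
#' mode the earlier segment of region A trains the model and the earlier
#' segment of region B is the test data; `cross_test = "later"` switches to
#' using region B's later segment instead (both conventions appear in the
#' source literature for this design, the earlier-segment one is the
#' default).
#'
#' @param segments_a list with `earlier`/`later` rasters from
#'   [segment_raster()] for region A.
#' @param segments_b same for region B (cross-region mode only).
#' @param mode `"same_region"` or `"cross_region"`.
#' @param cross_test which segment of region B tests a cross-region pair:
#'   `"earlier"` (default) or `"later"`.
#' @return list of class `segment_pair` with elements `train`, `test`,
#'   `pairing_mode`.
#' @export
make_segment_pair <- function(segments_a, segments_b = NULL,
                              mode = c("same_region", "cross_region"),
                              cross_test = c("earlier", "later")) {
  mode <- match.arg(mode)
  cross_test <- match.arg(cross_test)
  if (mode == "same_region") {
    train <- segments_a$earlier
    test <- segments_a$later
  } else {
    if (is.null(segments_b)) {
      abort("cross_region mode needs `segments_b`.")
    }
    train <- segments_a$earlier
    test <- segments_b[[cross_test]]
  }
  if (n_neurons(train) != n_neurons(test)) {
    abort(sprintf(
      "train and test must have the same neuron count (%d vs %d).",
      n_neurons(train), n_neurons(test)
    ))
  }
  if (train$bin_ms != test$bin_ms) {
    abort("train and test must share `bin_ms`.")
  }
  structure(list(train = train, test = test, pairing_mode = mode),
            class = "segment_pair")
}

#' Tidy a spike raster into an event list
#'
#' @param x a [spike_raster()].
#' @param ... unused.
#' @return tibble with one row per spike: `neuron_id`, `time_ms` (bin start),
#'   `bin` (1-based index), plus the neuron's `ei_type` and `layer`.
#' @export
tidy.spike_raster <- function(x, ...) {
  idx <- which(x$X == 1L, arr.ind = TRUE)
  meta <- x$neurons
  out <- tibble(
    neuron_id = meta$neuron_id[idx[, 2]],
    time_ms = x$t0_ms + (idx[, 1] - 1) * x$bin_ms,
    bin = as.integer(idx[, 1]),
    ei_type = meta$ei_type[idx[, 2]],
    layer = meta$layer[idx[, 2]]
  )
  arrange(out, .data$time_ms, .data$neuron_id)
}
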