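# Similarity between generated and real rasters: per-neuron firing rates and
# their correlation by cell class, the pairwise synchronization score against
# a binomial independence null, polar-quadrant histograms of the
# real-vs-generated score scatter, linear detrending, and sharpness.

#' Per-neuron firing rates
#'
#' @param raster a [spike_raster()].
#' @return tibble with `neuron_id`, `ei_type`, `layer`, `n_spikes` and
#'   `rate` (spikes/s = spike count / duration).
#' @export
firing_rate <- function(raster) {
  stopifnot(inherits(raster, "spike_raster"))
  dur <- duration_sec(raster)
  if (dur <= 0) abort("raster has zero duration.")
  counts <- colSums(raster$X)
  mutate(raster$neurons, n_spikes = as.integer(counts), rate = counts / dur)
}

#' Correlation of firing rates between real and generated data
#'
#' Pearson correlation of per-neuron firing rates across neurons, computed
#' for all neurons or restricted to one cell class. Undefined results (fewer
#' than 3 neurons, or zero variance in either vector) are flagged rather
#' than returned as NaN.
#'
#' @param real,gen [firing_rate()] tibbles over the same neurons.
#' @param subset `"all"`, `"inhibitory"` or `"excitatory"`.
#' @return one-row tibble: `subset`, `r`, `n`, `defined`.
#' @export
rate_correlation <- function(real, gen, subset = c("all", "inhibitory",
                                                   "excitatory")) {
  subset <- match.arg(subset)
  if (!identical(real$neuron_id, gen$neuron_id)) {
    abort("`real` and `gen` must cover the same neurons in the same order.")
  }
  keep <- if (subset == "all") rep(TRUE, nrow(real)) else real$ei_type == subset
  x <- real$rate[keep]
  y <- gen$rate[keep]
  defined <- length(x) >= 3 && sd(x) > 0 && sd(y) > 0
  tibble(subset = subset,
         r = if (defined) cor(x, y) else NA_real_,
         n = length(x), defined = defined)
}

#' Null probability of seeing a spike within the acceptable delay
#'
#' Under independence, the probability that a neuron with per-bin firing
#' probability `p` fires at least once within `D` bins after a reference
#' spike is `q = 1 - (1 - p)^D`.
#'
#' @param p per-bin firing probability (vectorised).
#' @param D acceptable delay in bins (integer >= 1).
#' @return the null probability `q`.
#' @export
sync_null_prob <- function(p, D) {
  if (any(D < 1) || any(D != round(D))) abort("`D` must be an integer >= 1.")
  if (any(p < 0 | p > 1)) abort("`p` must lie in [0, 1].")
  1 - (1 - p)^D
}

#' Pairwise synchronization score
#'
#' For every ordered neuron pair (source `i`, target `j`), counts how often
#' the target fires at least once within the `D` bins strictly after a
#' source spike (`C`), compares it with the binomial expectation under
#' independence (`N_i * q`, `q = 1 - (1 - p_j)^D` with `p_j` the target's
#' per-bin firing probability in the same raster), and standardises:
#' `Z = (C - N_i q) / sqrt(N_i q (1 - q))`. Positive scores indicate
#' co-occurrence, negative scores suppression. Pairs with a silent source
#' (`N_i = 0`) or degenerate null (`q` of 0 or 1), and the diagonal, are
#' flagged undefined.
#'
#' @param raster a [spike_raster()].
#' @param D acceptable delay in bins (default 1).
#' @param sqrt_denominator use the binomial standard deviation
#'   `sqrt(N q (1-q))` as the denominator (default TRUE). `FALSE` divides by
#'   the variance-like product `N q (1-q)` instead, for compatibility with a
#'   literal reading of the printed formula.
#' @param include_same_bin also count a target spike in the source's own bin
#'   (default FALSE: windows are `(t, t + D]`).
#' @return object of class `sync_score`: matrices `Z`, `C` and `defined`
#'   (source rows, target columns), vectors `N`, `p`, `q_bar`, plus `D` and
#'   the neuron metadata.
#' @export
sync_score <- function(raster, D = 1L, sqrt_denominator = TRUE,
                       include_same_bin = FALSE) {
  stopifnot(inherits(raster, "spike_raster"))
  if (D < 1 || D != round(D)) abort("`D` must be an integer >= 1.")
  X <- matrix(as.numeric(raster$X), nrow = n_bins(raster))
  Tn <- nrow(X)
  n <- ncol(X)
  N <- colSums(X)
  p <- N / Tn
  q_bar <- sync_null_prob(p, D)
  # Y[t, j] = 1 iff neuron j fires at least once in bins (t, t + D]
  Y <- matrix(0, Tn, n)
  for (d in seq_len(D)) {
    if (d < Tn) {
      shifted <- rbind(X[(1 + d):Tn, , drop = FALSE],
                       matrix(0, d, n))
      Y <- pmax(Y, shifted)
    }
  }
  if (include_same_bin) Y <- pmax(Y, X)
  C <- crossprod(X, Y)  # C[i, j] = windows of i containing a spike of j
  EC <- outer(N, q_bar)
  denom <- N %o% (q_bar * (1 - q_bar))
  if (sqrt_denominator) denom <- sqrt(denom)
  Z <- (C - EC) / denom
  defined <- outer(N > 0, q_bar > 0 & q_bar < 1, `&`)
  diag(defined) <- FALSE
  Z[!defined] <- NA_real_
  structure(
    list(Z = Z, C = C, N = N, p = p, q_bar = q_bar, defined = defined,
         D = as.integer(D), sqrt_denominator = sqrt_denominator,
         include_same_bin = include_same_bin, neurons = raster$neurons),
    class = "sync_score"
  )
}

#' @export
print.sync_score <- function(x, ...) {
  cat(sprintf(
    "<sync_score> %d neurons, D = %d bin(s): %d defined ordered pairs\n",
    length(x$N), x$D, sum(x$defined)))
  if (any(x$defined)) {
    zz <- x$Z[x$defined]
    cat(sprintf("  Z: mean %.3f, sd %.3f, range [%.2f, %.2f]\n",
                mean(zz), sd(zz), min(zz), max(zz)))
  }
  invisible(x)
}

#' @export
tidy.sync_score <- function(x, ...) {
  n <- length(x$N)
  grid <- expand.grid(source = seq_len(n), target = seq_len(n))
  out <- tibble(
    source = x$neurons$neuron_id[grid$source],
    target = x$neurons$neuron_id[grid$target],
    source_ei = x$neurons$ei_type[grid$source],
    C = as.vector(x$C), Z = as.vector(x$Z),
    defined = as.vector(x$defined)
  )
  filter(out, .data$source != .data$target)
}

#' Polar-quadrant histogram of real-vs-generated synchronization scores
#'
#' Every ordered pair defined in both matrices becomes a point
#' `(Z_real, Z_gen)`; in rotational coordinates `theta = atan2(Z_gen,
#' Z_real)` mapped to `[0, 2pi)` and `r` the radius. Points whose angle
#' falls in the requested quadrant (Q1 = `[0, pi/2)`, where both scores are
#' positive; Q3 = `[pi, 3pi/2)`, both negative — characteristic of
#' inhibitory sources) are kept and binned into an angular histogram.
#' Successful generation concentrates mass near the diagonal (`pi/4` in Q1,
#' `5pi/4` in Q3).
#'
#' @param real_sync,gen_sync [sync_score()] objects over the same neurons.
#' @param quadrant `"Q1"` or `"Q3"`.
#' @param bin_width angular bin width in radians (default `pi / 90`, i.e.
#'   2 degrees; must tile the quadrant's pi/2 range to within rounding).
#' @return object of class `polar_quadrant`: tibble `points`
#'   (`theta`, `r`, `z_real`, `z_gen`), tibble `histogram` (`bin_mid`,
#'   `count`), the quadrant bounds, `bin_width`, and `detrended` flag.
#' @export
polar_quadrant <- function(real_sync, gen_sync, quadrant = c("Q1", "Q3"),
                           bin_width = pi / 90) {
  quadrant <- match.arg(quadrant)
  stopifnot(inherits(real_sync, "sync_score"), inherits(gen_sync, "sync_score"))
  both <- real_sync$defined & gen_sync$defined
  zr <- real_sync$Z[both]
  zg <- gen_sync$Z[both]
  theta <- atan2(zg, zr) %% (2 * pi)
  r <- sqrt(zr^2 + zg^2)
  lo <- if (quadrant == "Q1") 0 else pi
  hi <- lo + pi / 2
  keep <- theta >= lo & theta < hi
  n_bins <- round((pi / 2) / bin_width)
  if (abs(n_bins * bin_width - pi / 2) > 1e-9) {
    abort("`bin_width` must divide the quadrant range pi/2.")
  }
  breaks <- lo + bin_width * (0:n_bins)
  counts <- tabulate(findInterval(theta[keep], breaks,
                                  rightmost.closed = FALSE),
                     nbins = n_bins)
  if (!any(keep)) {
    warn(sprintf("no points fall in quadrant %s.", quadrant))
  }
  structure(
    list(points = tibble(theta = theta[keep], r = r[keep],
                         z_real = zr[keep], z_gen = zg[keep]),
         histogram = tibble(bin_mid = (head(breaks, -1) + tail(breaks, -1)) / 2,
                            count = as.numeric(counts)),
         quadrant = quadrant, lo = lo, hi = hi, bin_width = bin_width,
         detrended = FALSE, empty = !any(keep)),
    class = "polar_quadrant"
  )
}

#' @export
print.polar_quadrant <- function(x, ...) {
  cat(sprintf(
    "<polar_quadrant> %s [%.3f, %.3f): %d points, %d bins of %.1f deg%s\n",
    x$quadrant, x$lo, x$hi, nrow(x$points), nrow(x$histogram),
    x$bin_width * 180 / pi, if (x$detrended) ", detrended" else ""))
  invisible(x)
}

#' Remove the linear trend of a quadrant histogram
#'
#' Fits a least-squares line to (bin centre, count) and removes only the
#' slope: returned counts are `count - slope * (centre - mean(centre))`, so
#' the histogram mean is preserved. Detrending precedes peak location in the
#' sharpness computation.
#'
#' @param hist a [polar_quadrant()] object with at least 2 bins.
#' @return the same object with detrended counts and `detrended = TRUE`.
#' @export
detrend_histogram <- function(hist) {
  stopifnot(inherits(hist, "polar_quadrant"))
  h <- hist$histogram
  if (nrow(h) < 2) abort("detrending needs at least 2 bins.")
  slope <- coef(lm(count ~ bin_mid, data = h))[[2]]
  hist$histogram$count <- h$count - slope * (h$bin_mid - mean(h$bin_mid))
  hist$detrended <- TRUE
  hist
}

#' Sharpness of a quadrant histogram
#'
#' Ratio of the histogram area inside a `pi/4`-wide window centred on the
#' peak to the area at the other angles of the quadrant. The peak is the bin
#' with the maximal (detrended) count, ties broken toward the quadrant
#' centre; the window is clipped at the quadrant edges; negative detrended
#' counts are floored at zero before areas are computed. A uniform histogram
#' has sharpness 1 (up to bin discretisation); if all mass lies inside the
#' window the result is `Inf` with a warning.
#'
#' @param hist a [polar_quadrant()] histogram; detrended first if it is not
#'   already (with a message).
#' @param detrend detrend before measuring (default TRUE if not yet done).
#' @return one-row tibble: `quadrant`, `sharpness`, `peak_theta`,
#'   `bin_width`, `n_points`.
#' @export
sharpness <- function(hist, detrend = !hist$detrended) {
  stopifnot(inherits(hist, "polar_quadrant"))
  if (detrend && !hist$detrended) hist <- detrend_histogram(hist)
  h <- hist$histogram
  counts <- pmax(h$count, 0)
  mid <- h$bin_mid
  centre <- (hist$lo + hist$hi) / 2
  best <- max(counts)
  cand <- which(counts == best)
  cand <- cand[order(abs(mid[cand] - centre), mid[cand])]
  peak <- cand[1]
  win_lo <- max(hist$lo, mid[peak] - pi / 8)
  win_hi <- min(hist$hi, mid[peak] + pi / 8)
  bw <- hist$bin_width
  bin_lo <- mid - bw / 2
  bin_hi <- mid + bw / 2
  overlap <- pmax(0, pmin(bin_hi, win_hi) - pmax(bin_lo, win_lo))
  area_in <- sum(counts * overlap)
  area_out <- sum(counts * (bw - overlap))
  if (area_out <= 0) {
    warn("all histogram mass lies inside the peak window; sharpness is Inf.")
    sharp <- Inf
  } else {
    sharp <- area_in / area_out
  }
  tibble(quadrant = hist$quadrant, sharpness = sharp, peak_theta = mid[peak],
         bin_width = bw, n_points = nrow(hist$points))
}

#' Evaluate a generated raster against the real test raster
#'
#' Bundles the evaluation used throughout: firing-rate correlations for all,
#' inhibitory-only and excitatory-only neurons; synchronization-score
#' matrices of both rasters; and the Q1/Q3 sharpness of the
#' real-versus-generated score scatter. Component failures (for example a
#' quadrant with no points) are flagged in the output, not fatal.
#'
#' @param real_test the real test-segment [spike_raster()].
#' @param generated the generated [spike_raster()], same neurons and same
#'   number of bins (crop the real raster with [crop_raster()] to match the
#'   generator's warm-up if needed).
#' @param D acceptable delay for the synchronization score (default 1 bin).
#' @param bin_width angular histogram bin width (default `pi / 90`).
#' @param sqrt_denominator passed to [sync_score()].
#' @return object of class `generation_eval` with `rate_cor` (tibble),
#'   `sharpness` (tibble), `rates` (per-neuron tibble), `sync`
#'   (list of the two [sync_score()]s) and `quadrants` (list of
#'   [polar_quadrant()]s).
#' @export
evaluate_pair <- function(real_test, generated, D = 1L, bin_width = pi / 90,
                          sqrt_denominator = TRUE) {
  stopifnot(inherits(real_test, "spike_raster"),
            inherits(generated, "spike_raster"))
  if (!identical(real_test$neurons$neuron_id, generated$neurons$neuron_id)) {
    abort("real and generated rasters must cover the same neurons.")
  }
  if (n_bins(real_test) != n_bins(generated)) {
    abort(sprintf(
      "real and generated rasters must have the same bins (%d vs %d); crop the real raster to the generated window.",
      n_bins(real_test), n_bins(generated)))
  }
  fr_real <- firing_rate(real_test)
  fr_gen <- firing_rate(generated)
  rate_cor <- bind_rows(
    rate_correlation(fr_real, fr_gen, "all"),
    rate_correlation(fr_real, fr_gen, "inhibitory"),
    rate_correlation(fr_real, fr_gen, "excitatory")
  )
  zs_real <- sync_score(real_test, D = D, sqrt_denominator = sqrt_denominator)
  zs_gen <- sync_score(generated, D = D, sqrt_denominator = sqrt_denominator)
  quadrants <- list()
  sharp <- list()
  for (q in c("Q1", "Q3")) {
    pq <- withCallingHandlers(
      polar_quadrant(zs_real, zs_gen, q, bin_width = bin_width),
      warning = function(w) invokeRestart("muffleWarning")
    )
    quadrants[[q]] <- pq
    sharp[[q]] <- if (pq$empty) {
      tibble(quadrant = q, sharpness = NA_real_, peak_theta = NA_real_,
             bin_width = bin_width, n_points = 0L)
    } else {
      suppressWarnings(sharpness(pq))
    }
  }
  rates <- tibble(
    neuron_id = fr_real$neuron_id, ei_type = fr_real$ei_type,
    rate_real = fr_real$rate, rate_gen = fr_gen$rate
  )
  structure(
    list(rate_cor = rate_cor, sharpness = bind_rows(sharp), rates = rates,
         sync = list(real = zs_real, generated = zs_gen),
         quadrants = quadrants, D = as.integer(D), bin_width = bin_width),
    class = "generation_eval"
  )
}

#' @export
print.generation_eval <- function(x, ...) {
  cat("<generation_eval>\n  rate correlations:\n")
  for (i in seq_len(nrow(x$rate_cor))) {
    cat(sprintf("    %-11s r = %s (n = %d)\n", x$rate_cor$subset[i],
                ifelse(x$rate_cor$defined[i],
                       sprintf("%.3f", x$rate_cor$r[i]), "undefined"),
                x$rate_cor$n[i]))
  }
  cat("  sharpness:\n")
  for (i in seq_len(nrow(x$sharpness))) {
    cat(sprintf("    %s = %s (%d points)\n", x$sharpness$quadrant[i],
                ifelse(is.na(x$sharpness$sharpness[i]), "undefined",
                       sprintf("%.2f", x$sharpness$sharpness[i])),
                x$sharpness$n_points[i]))
  }
  invisible(x)
}

#' @export
tidy.generation_eval <- function(x, ...) {
  bind_rows(
    mutate(select(x$rate_cor, metric = .data$subset, value = .data$r),
           family = "rate_correlation"),
    tibble(metric = x$sharpness$quadrant, value = x$sharpness$sharpness,
           family = "sharpness")
  )
}

#' @export
glance.generation_eval <- function(x, ...) {
  rc <- x$rate_cor
  sh <- x$sharpness
  tibble(
    rate_cor_all = rc$r[rc$subset == "all"],
    rate_cor_inh = rc$r[rc$subset == "inhibitory"],
    rate_cor_exc = rc$r[rc$subset == "excitatory"],
    sharp_q1 = sh$sharpness[sh$quadrant == "Q1"],
    sharp_q3 = sh$sharpness[sh$quadrant == "Q3"],
    D = x$D, bin_width = x$bin_width
  )
}
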