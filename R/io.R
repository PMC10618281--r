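#' Read and write spike rasters
#'
#' Two plain-text formats are supported, each accompanied by a YAML sidecar
#' (`<path>.yaml`) holding `bin_ms`, `t0_ms`, `n_bins`, the neuron metadata
#' and an optional region label:
#'
#' * **events** (`.tsv`): one spike per line, `neuron_id<TAB>time_ms`.
#'   Reading bins each spike into `floor((time_ms - t0_ms) / bin_ms)`;
#'   multiple spikes of one neuron in one bin collapse to a single 1.
#' * **dense** (`.dense.tsv`): the full 0/1 matrix, one row per time bin,
#'   tab-separated, no header. Suited to short or dense rasters.
#'
#' `write_raster()` followed by `read_raster()` reproduces the matrix,
#' metadata, `bin_ms` and `t0_ms` exactly in both formats.
#'
#' @param path file path. `format = "auto"` treats `*.dense.tsv` as dense
#'   and any other `*.tsv` as an event list.
#' @param format one of `"auto"`, `"events"`, `"dense"`.
#' @param raster a [spike_raster()].
#' @return `read_raster()` returns a [spike_raster()]; `write_raster()`
#'   returns `path` invisibly.
#' @export
read_raster <- function(path, format = c("auto", "events", "dense")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  format <- resolve_format(path, format)
  side <- read_sidecar(path)
  neurons <- validate_neuron_meta(side$neurons)
  if (format == "dense") {
    X <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                     colClasses = "integer"))
    dimnames(X) <- NULL
  } else {
    X <- read_event_matrix(path, side, neurons)
  }
  spike_raster(X, neurons = neurons, bin_ms = side$bin_ms,
               t0_ms = side$t0_ms, region = side$region)
}

#' @rdname read_raster
#' @export
write_raster <- function(raster, path, format = c("auto", "events", "dense")) {
  stopifnot(inherits(raster, "spike_raster"))
  format <- resolve_format(path, match.arg(format))
  if (format == "dense") {
    utils::write.table(raster$X, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  } else {
    idx <- which(raster$X == 1L, arr.ind = TRUE)
    ord <- order(idx[, 1], idx[, 2])
    idx <- idx[ord, , drop = FALSE]
    lines <- sprintf("%d\t%s",
                     raster$neurons$neuron_id[idx[, 2]],
                     format(raster$t0_ms + (idx[, 1] - 1) * raster$bin_ms,
                            scientific = FALSE, trim = TRUE))
    writeLines(lines, path)
  }
  write_sidecar(raster, path)
  invisible(path)
}

resolve_format <- function(path, format) {
  if (format != "auto") return(format)
  if (grepl("\\.dense\\.tsv$", path)) "dense" else "events"
}

sidecar_path <- function(path) paste0(path, ".yaml")

write_sidecar <- function(raster, path) {
  meta <- list(
    format_version = 1L,
    bin_ms = raster$bin_ms,
    t0_ms = raster$t0_ms,
    n_bins = n_bins(raster),
    region = if (is.null(raster$region)) NULL else unclass(raster$region),
    neurons = purrr::pmap(raster$neurons, function(neuron_id, ei_type, layer) {
      list(neuron_id = neuron_id, ei_type = ei_type, layer = layer)
    })
  )
  yaml::write_yaml(meta, sidecar_path(path))
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) {
    abort(paste0("missing metadata sidecar: ", sp))
  }
  side <- yaml::read_yaml(sp)
  side$neurons <- purrr::map_dfr(side$neurons, as_tibble)
  if (!is.null(side$region)) {
    side$region <- validate_region_label(side$region)
  }
  side
}

read_event_matrix <- function(path, side, neurons) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  n <- nrow(neurons)
  X <- matrix(0L, nrow = side$n_bins, ncol = n)
  if (length(lines) == 0) return(X)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0) {
    abort(sprintf("malformed event at line %d of %s: %s",
                  bad[1], path, lines[bad[1]]))
  }
  ids <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1L)))
  times <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- which(is.na(ids) | is.na(times))
  if (length(bad) > 0) {
    abort(sprintf("malformed event at line %d of %s: %s",
                  bad[1], path, lines[bad[1]]))
  }
  if (any(times < side$t0_ms)) {
    abort(sprintf("spike time before t0 (%g ms) at line %d of %s",
                  side$t0_ms, which(times < side$t0_ms)[1], path))
  }
  col <- match(ids, neurons$neuron_id)
  if (anyNA(col)) {
    abort(sprintf("unknown neuron_id %d at line %d of %s",
                  ids[which(is.na(col))[1]], which(is.na(col))[1], path))
  }
  bin <- floor((times - side$t0_ms) / side$bin_ms) + 1
  if (any(bin > side$n_bins)) {
    abort(sprintf("spike time beyond raster end at line %d of %s",
                  which(bin > side$n_bins)[1], path))
  }
  X[cbind(bin, col)] <- 1L
  X
}
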