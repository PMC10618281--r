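# Cross-region generation matrices, hierarchical-clustering sorts, and the
# comparison of generation quality with anatomy (Mann-Whitney U on angle
# groups, correlation with structural connection strength, Bonferroni x4).

cross_gen_metrics <- c("rate_cor_all", "rate_cor_inh", "rate_cor_exc",
                       "sharp_q1", "sharp_q3")

#' Assemble the cross-region generation matrix
#'
#' Takes one row per evaluated (source region, target region, dataset) with
#' the five summary metrics (as produced by `glance()` on a
#' [evaluate_pair()] result) and arranges them into square region-by-region
#' grids. When both replicate datasets provide a pair, their values are
#' averaged elementwise; pairs never evaluated stay `NA`.
#'
#' @param evals tibble with columns `source`, `target`, `dataset` and the
#'   metrics `rate_cor_all`, `rate_cor_inh`, `rate_cor_exc`, `sharp_q1`,
#'   `sharp_q3` (missing metric columns are allowed and skipped).
#' @return object of class `cross_gen_matrix`: named list `metrics` of
#'   matrices (source rows, target columns), the region set, datasets seen
#'   and an `averaged` flag.
#' @export
build_matrix <- function(evals) {
  req <- c("source", "target", "dataset")
  if (!all(req %in% names(evals)) || nrow(evals) == 0) {
    abort("`evals` needs at least one row and columns source, target, dataset.")
  }
  dup <- duplicated(evals[, req])
  if (any(dup)) {
    abort("duplicate (source, target, dataset) rows in `evals`.")
  }
  metrics <- intersect(cross_gen_metrics, names(evals))
  if (length(metrics) == 0) abort("`evals` carries none of the known metrics.")
  regions <- sort(unique(c(evals$source, evals$target)))
  datasets <- sort(unique(evals$dataset))
  grids <- purrr::map(metrics, function(m) {
    per_ds <- purrr::map(datasets, function(d) {
      g <- matrix(NA_real_, length(regions), length(regions),
                  dimnames = list(regions, regions))
      rows <- evals[evals$dataset == d, ]
      g[cbind(match(rows$source, regions), match(rows$target, regions))] <-
        rows[[m]]
      g
    })
    acc <- matrix(0, length(regions), length(regions),
                  dimnames = list(regions, regions))
    cnt <- acc
    for (g in per_ds) {
      ok <- !is.na(g)
      acc[ok] <- acc[ok] + g[ok]
      cnt <- cnt + ok
    }
    out <- acc / cnt
    out[cnt == 0] <- NA_real_
    out
  })
  names(grids) <- metrics
  structure(
    list(metrics = grids, regions = regions, datasets = datasets,
         averaged = length(datasets) > 1),
    class = "cross_gen_matrix"
  )
}

#' @export
print.cross_gen_matrix <- function(x, ...) {
  cat(sprintf(
    "<cross_gen_matrix> %d regions x %d regions; metrics: %s; datasets: %s%s\n",
    length(x$regions), length(x$regions),
    paste(names(x$metrics), collapse = ", "),
    paste(x$datasets, collapse = ", "),
    if (x$averaged) " (averaged)" else ""))
  invisible(x)
}

#' @export
tidy.cross_gen_matrix <- function(x, ...) {
  purrr::imap_dfr(x$metrics, function(g, m) {
    grid <- expand.grid(source = x$regions, target = x$regions,
                        stringsAsFactors = FALSE)
    tibble(metric = m, source = grid$source, target = grid$target,
           value = g[cbind(grid$source, grid$target)])
  })
}

#' Order regions by hierarchical clustering of a metric grid
#'
#' Agglomerative clustering (average linkage on the Euclidean distance
#' between grid rows); the returned region order is the dendrogram's leaf
#' order, which is deterministic for a given grid. Used to sort the colour
#' maps so regions with similar generation profiles sit together.
#'
#' @param x a [build_matrix()] object.
#' @param metric which grid to cluster on (default the first).
#' @return character vector: the regions in leaf order.
#' @export
cluster_sort <- function(x, metric = names(x$metrics)[1]) {
  stopifnot(inherits(x, "cross_gen_matrix"))
  g <- x$metrics[[metric]]
  if (is.null(g)) abort(paste0("no such metric grid: ", metric))
  if (anyNA(g)) {
    abort("metric grid has missing pairs; evaluate them or subset the regions before clustering.")
  }
  if (nrow(g) == 1) return(rownames(g))
  hc <- hclust(dist(g), method = "average")
  rownames(g)[hc$order]
}

#' Compare generation quality with anatomy
#'
#' For one hemisphere and one metric grid, assembles per-pair rows (metric
#' value, relative-angle score, structural connection strength) and runs the
#' two tests: a two-sided Mann-Whitney U between the metric values of
#' angle-0 pairs (the same-region diagonal) and angle-1 pairs, and the
#' Pearson correlation (Spearman also reported) between metric and
#' connection strength. Raw p values are Bonferroni-corrected with factor 4
#' (the number of panels the test is repeated over), capped at 1.
#'
#' @param x a [build_matrix()] object.
#' @param anatomy tibble with columns `source`, `target`, `angle_score`,
#'   `strength` (and optionally `hemisphere`), e.g. derived from
#'   [anatomy_pairs()]; regions must match the grid's names.
#' @param metric metric grid name (default the first).
#' @param hemisphere optional filter applied to `anatomy$hemisphere`.
#' @param bonferroni_n correction factor (default 4).
#' @return object of class `anatomy_comparison` with tibbles `rows` and
#'   `tests`.
#' @export
compare_with_anatomy <- function(x, anatomy, metric = names(x$metrics)[1],
                                 hemisphere = NULL, bonferroni_n = 4) {
  stopifnot(inherits(x, "cross_gen_matrix"))
  g <- x$metrics[[metric]]
  if (is.null(g)) abort(paste0("no such metric grid: ", metric))
  need <- c("source", "target", "angle_score", "strength")
  if (!all(need %in% names(anatomy))) {
    abort(paste0("`anatomy` needs columns: ", paste(need, collapse = ", ")))
  }
  rows <- anatomy
  if (!is.null(hemisphere) && "hemisphere" %in% names(rows)) {
    rows <- rows[rows$hemisphere == hemisphere, ]
  }
  rows <- rows[rows$source %in% x$regions & rows$target %in% x$regions, ]
  rows$value <- g[cbind(rows$source, rows$target)]
  rows <- rows[!is.na(rows$value), ]
  if (nrow(rows) == 0) abort("no anatomy pairs match the metric grid.")

  g0 <- rows$value[rows$angle_score == 0]
  g1 <- rows$value[rows$angle_score == 1]
  if (length(g0) >= 2 && length(g1) >= 2) {
    u <- suppressWarnings(wilcox.test(g0, g1, alternative = "two.sided"))
    u_row <- tibble(test = "mann_whitney_angle0_vs_angle1",
                    statistic = unname(u$statistic), estimate = NA_real_,
                    p_raw = u$p.value,
                    n = length(g0) + length(g1), skipped = FALSE)
  } else {
    u_row <- tibble(test = "mann_whitney_angle0_vs_angle1",
                    statistic = NA_real_, estimate = NA_real_,
                    p_raw = NA_real_, n = length(g0) + length(g1),
                    skipped = TRUE)
  }
  cor_rows <- purrr::map_dfr(c("pearson", "spearman"), function(meth) {
    ok <- is.finite(rows$strength) & is.finite(rows$value)
    if (sum(ok) >= 3 && sd(rows$value[ok]) > 0 && sd(rows$strength[ok]) > 0) {
      ct <- suppressWarnings(cor.test(rows$strength[ok], rows$value[ok],
                                      method = meth))
      tibble(test = paste0(meth, "_strength"),
             statistic = unname(ct$statistic),
             estimate = unname(ct$estimate), p_raw = ct$p.value,
             n = sum(ok), skipped = FALSE)
    } else {
      tibble(test = paste0(meth, "_strength"), statistic = NA_real_,
             estimate = NA_real_, p_raw = NA_real_, n = sum(ok),
             skipped = TRUE)
    }
  })
  tests <- bind_rows(u_row, cor_rows)
  tests$p_bonferroni <- pmin(1, bonferroni_n * tests$p_raw)
  structure(
    list(rows = as_tibble(rows), tests = tests, metric = metric,
         hemisphere = hemisphere, bonferroni_n = bonferroni_n),
    class = "anatomy_comparison"
  )
}

#' @export
print.anatomy_comparison <- function(x, ...) {
  cat(sprintf("<anatomy_comparison> metric %s%s, %d pairs\n", x$metric,
              if (is.null(x$hemisphere)) "" else paste0(", hemisphere ",
                                                        x$hemisphere),
              nrow(x$rows)))
  print(x$tests)
  invisible(x)
}

#' @export
tidy.anatomy_comparison <- function(x, ...) x$tests

#' Write the report bundle
#'
#' Writes the metric grids as CSV (one per metric, regions sorted by
#' [cluster_sort()] where the grid is complete), the anatomy-comparison test
#' results as JSON, figure files for the grids and comparisons, and a
#' provenance file recording the seed and a hash of the configuration.
#' Refuses to overwrite a non-empty directory unless `force = TRUE`.
#' Re-running with identical inputs reproduces the CSV/JSON files byte for
#' byte.
#'
#' @param x a [build_matrix()] object.
#' @param comparisons list of [compare_with_anatomy()] results (possibly
#'   empty).
#' @param out_dir output directory.
#' @param seed,config recorded in `provenance.json`.
#' @param force overwrite an existing non-empty directory.
#' @param figures also write PNG figures (default TRUE).
#' @return invisibly, a character vector of the files written.
#' @export
report_bundle <- function(x, comparisons = list(), out_dir, seed = NULL,
                          config = NULL, force = FALSE, figures = TRUE) {
  stopifnot(inherits(x, "cross_gen_matrix"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    abort(paste0("output directory is not empty (use force = TRUE): ",
                 out_dir))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (m in names(x$metrics)) {
    g <- x$metrics[[m]]
    if (!anyNA(g)) {
      ord <- cluster_sort(x, m)
      g <- g[ord, ord]
    }
    f <- file.path(out_dir, paste0("grid_", m, ".csv"))
    utils::write.csv(as.data.frame(g), f)
    written <- c(written, f)
  }
  if (length(comparisons) > 0) {
    tests <- purrr::imap_dfr(comparisons, function(cmp, nm) {
      mutate(cmp$tests, metric = cmp$metric,
             hemisphere = cmp$hemisphere %||% NA_character_,
             panel = as.character(nm))
    })
    f <- file.path(out_dir, "anatomy_tests.json")
    jsonlite::write_json(tests, f, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
    written <- c(written, f)
    f <- file.path(out_dir, "anatomy_pairs.csv")
    pairs <- purrr::imap_dfr(comparisons, function(cmp, nm) {
      mutate(cmp$rows, metric = cmp$metric, panel = as.character(nm))
    })
    utils::write.csv(pairs, f, row.names = FALSE)
    written <- c(written, f)
  } else {
    f <- file.path(out_dir, "anatomy_tests.json")
    jsonlite::write_json(list(), f, auto_unbox = TRUE)
    written <- c(written, f)
  }
  prov <- list(
    package = "spikegen",
    version = as.character(utils::packageVersion("spikegen")),
    seed = seed,
    config_hash = if (is.null(config)) NULL else digest::digest(config),
    written_at = "see file system; timestamps omitted for reproducibility"
  )
  f <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, f, auto_unbox = TRUE, pretty = TRUE, null = "null")
  written <- c(written, f)
  if (figures) {
    for (m in names(x$metrics)) {
      f <- file.path(out_dir, paste0("grid_", m, ".png"))
      grDevices::png(f, width = 900, height = 800, res = 120)
      print(autoplot(x, metric = m))
      grDevices::dev.off()
      written <- c(written, f)
    }
    for (nm in names(comparisons)) {
      cmp <- comparisons[[nm]]
      f <- file.path(out_dir, paste0("anatomy_", nm, ".png"))
      grDevices::png(f, width = 1200, height = 500, res = 120)
      print(autoplot(cmp))
      grDevices::dev.off()
      written <- c(written, f)
    }
  }
  invisible(written)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
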