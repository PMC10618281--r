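# ggplot2 views of the result objects. Each autoplot() returns a ggplot so
# callers can restyle; plot_* helpers compose multi-panel summaries.

#' @export
autoplot.lstm_model <- function(object, ...) {
  trace <- tidyr::pivot_longer(object$trace, c("train_loss", "val_loss"),
                               names_to = "series", values_to = "loss")
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                      colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(train_loss = "#1b6ca8", val_loss = "#d1495b"),
      labels = c(train_loss = "training", val_loss = "validation"),
      name = NULL) +
    ggplot2::labs(x = "epoch", y = "mean focal loss",
                  title = "Training and validation loss") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.polar_quadrant <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = object$bin_width, fill = "#1b6ca8") +
    ggplot2::labs(
      x = expression(theta ~ "(rad)"), y = "pairs",
      title = sprintf("%s angular histogram%s", object$quadrant,
                      if (object$detrended) " (detrended)" else "")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.generation_eval <- function(object,
                                     type = c("rates", "sync", "histogram"),
                                     quadrant = "Q1", ...) {
  type <- match.arg(type)
  if (type == "rates") {
    ggplot2::ggplot(object$rates,
                    ggplot2::aes(x = .data$rate_real, y = .data$rate_gen,
                                 colour = .data$ei_type)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                           colour = "grey50") +
      ggplot2::geom_point(alpha = 0.8) +
      ggplot2::labs(x = "firing rate, real test data (spikes/s)",
                    y = "firing rate, generated data (spikes/s)",
                    colour = NULL) +
      ggplot2::theme_minimal()
  } else if (type == "sync") {
    both <- object$sync$real$defined & object$sync$generated$defined
    df <- tibble(z_real = object$sync$real$Z[both],
                 z_gen = object$sync$generated$Z[both])
    ggplot2::ggplot(df, ggplot2::aes(x = .data$z_real, y = .data$z_gen)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                           colour = "grey50") +
      ggplot2::geom_point(alpha = 0.4, size = 0.8) +
      ggplot2::labs(x = "synchronization score, real test data",
                    y = "synchronization score, generated data") +
      ggplot2::theme_minimal()
  } else {
    autoplot(object$quadrants[[quadrant]])
  }
}

#' @export
autoplot.cross_gen_matrix <- function(object, metric = names(object$metrics)[1],
                                      sort = TRUE, ...) {
  g <- object$metrics[[metric]]
  if (is.null(g)) abort(paste0("no such metric grid: ", metric))
  if (sort && !anyNA(g)) {
    ord <- cluster_sort(object, metric)
    g <- g[ord, ord]
  }
  df <- tidyr::expand_grid(source = rownames(g), target = colnames(g))
  df$value <- g[cbind(df$source, df$target)]
  df$source <- factor(df$source, levels = rev(rownames(g)))
  df$target <- factor(df$target, levels = colnames(g))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target, y = .data$source,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(x = "target region", y = "source region", fill = metric,
                  title = sprintf("Cross-region generation: %s", metric)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.anatomy_comparison <- function(object, ...) {
  rows <- tidyr::pivot_longer(object$rows, c("angle_score", "strength"),
                              names_to = "against", values_to = "x")
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "#d1495b", linewidth = 0.5) +
    ggplot2::facet_wrap(~against, scales = "free_x") +
    ggplot2::labs(x = NULL, y = object$metric,
                  title = "Generation quality vs anatomy") +
    ggplot2::theme_minimal()
}

#' Raster dot plot
#'
#' @param raster a [spike_raster()].
#' @param max_bins cap on plotted bins (from the start) to keep figures
#'   light (default 20000).
#' @return a ggplot.
#' @export
plot_raster <- function(raster, max_bins = 20000) {
  r <- crop_raster(raster, 1L, min(n_bins(raster), max_bins))
  ev <- tidy(r)
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$time_ms / 1000,
                                   y = factor(.data$neuron_id),
                                   colour = .data$ei_type)) +
    ggplot2::geom_point(shape = "|", size = 1.5) +
    ggplot2::labs(x = "time (s)", y = "neuron", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
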