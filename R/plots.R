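#' Plot a threshold scan
#'
#' Shows the false-discovery proxy and the penalised objective over the
#' candidate frequency thresholds, with the chosen `t*` marked.
#'
#' @param object A `threshold_scan` from [choose_threshold()] or
#'   `attr(fdpp_aggregate(...), "scan")`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.threshold_scan <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy(object), cols = c("fdp_plus", "objective"),
                            names_to = "curve", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value,
                                   colour = .data$curve)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "t_star"),
                        linetype = "dashed") +
    ggplot2::labs(x = "frequency threshold t", y = NULL,
                  title = sprintf("Threshold scan (t* = %.3g)",
                                  attr(object, "t_star"))) +
    ggplot2::theme_minimal()
}

#' Plot an ensemble result
#'
#' Score against score rank, selected genes highlighted; for the frequency
#' ensemble the controls are drawn separately per origin.
#'
#' @param object An `ensemble_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ensemble_result <- function(object, ...) {
  df <- tidy(object)
  df$rank <- rank(-df$score, ties.method = "first")
  aes <- ggplot2::aes(x = .data$rank, y = .data$score,
                      colour = .data$selected)
  p <- ggplot2::ggplot(df, aes) + ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "score rank", y = "score",
                  title = attr(object, "method")) +
    ggplot2::theme_minimal()
  if ("origin" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(~origin)
  }
  p
}

#' Spatial expression map of one gene
#'
#' @inheritParams moran_detector
#' @param gene Gene id to display.
#' @return A ggplot object.
#' @export
plot_expression <- function(ds, gene) {
  stopifnot(inherits(ds, "spatial_dataset"))
  if (!gene %in% gene_ids(ds)) abort(paste0("Unknown gene: ", gene))
  df <- ds$coords
  df$value <- as.numeric(ds$expr[gene, ])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$value)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_viridis_c(name = gene) +
    ggplot2::coord_equal() + ggplot2::theme_minimal()
}

#' Plot a simulation sweep
#'
#' Mean metric with 95% confidence ribbons per method over the swept
#' parameter values (the Fig-2-style benchmark view).
#'
#' @param sweep Result of [sweep_simulation()].
#' @param metric Metric column to display (default `"f1"`).
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, metric = "f1") {
  df <- filter(sweep$summary, .data$metric == !!metric)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$mean,
                                   colour = .data$method,
                                   fill = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo,
                                      ymax = .data$ci_hi),
                         alpha = 0.15, colour = NA) +
    ggplot2::labs(x = df$parameter[1L], y = metric) +
    ggplot2::theme_minimal()
}
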