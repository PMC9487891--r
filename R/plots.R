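#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a PLI connectivity matrix
#'
#' @param object A `pli_array` from [pli_matrix()].
#' @param epoch Epoch to display (default: mean across epochs).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pli_array
#' @export
autoplot.pli_array <- function(object, epoch = NULL, ...) {
  m <- if (is.null(epoch)) {
    apply(unclass(object), c(2, 3), mean)
  } else {
    pli_epoch(object, epoch)
  }
  labs <- dimnames(object)[[2]]
  df <- tidyr::expand_grid(a = seq_along(labs), b = seq_along(labs))
  df$pli <- m[cbind(df$a, df$b)]
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b, fill = .data$pli)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "channel", y = "channel", fill = "PLI",
      title = sprintf("PLI connectivity (%s band%s)",
                      attr(object, "band") %||% "?",
                      if (is.null(epoch)) ", epoch mean"
                      else paste0(", epoch ", epoch))
    )
}

#' Group-by-condition panel plot of an MST metric
#'
#' Boxplots of a subject-level metric by group and condition, optionally
#' faceted by band, mirroring the standard presentation of tree-topology
#' group comparisons.
#'
#' @param panel Subject-level metric panel (from [run_pipeline()]'s
#'   `metrics`, or [aggregate_epochs()] joined with a subject table).
#' @param metric Metric column name.
#' @param bands Optional band subset.
#' @return A ggplot.
#' @export
plot_metric_by_group <- function(panel, metric, bands = NULL) {
  stopifnot(metric %in% names(panel))
  if (!is.null(bands)) panel <- panel[panel$band %in% bands, ]
  p <- ggplot2::ggplot(panel, ggplot2::aes(.data$condition,
                                           .data[[metric]],
                                           fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "condition", y = metric, fill = "group")
  if ("band" %in% names(panel) && length(unique(panel$band)) > 1) {
    p <- p + ggplot2::facet_wrap(~band, scales = "free_y")
  }
  p
}

#' Scatter plot of behaviour against a tree metric
#'
#' @param panel Subject-level rows (one condition and band).
#' @param metric Metric column.
#' @param behavior Behaviour column (default `"acc"`).
#' @return A ggplot with a per-group linear trend.
#' @export
plot_behavior_correlation <- function(panel, metric, behavior = "acc") {
  ggplot2::ggplot(panel, ggplot2::aes(.data[[metric]], .data[[behavior]],
                                      colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = metric, y = behavior)
}
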