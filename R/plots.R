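# ggplot2 views of the main result types.

#' Group mean metric curves across the threshold grid
#'
#' Plots, for each global metric, the group mean (with a +/- 1 SE ribbon)
#' against the binarization threshold — the standard way to show that a
#' group difference is not an artefact of one threshold choice.
#'
#' @param metrics A per-subject metric table with columns `subject_id`,
#'   `group`, `threshold`, `metric`, `node`, `value`.
#' @param which_metrics Metrics to show (defaults to the three global ones).
#' @return A ggplot object.
#' @export
plot_metric_curves <- function(metrics,
                               which_metrics = c("global_efficiency",
                                                 "connection_cost",
                                                 "mean_clustering")) {
  d <- metrics |>
    dplyr::filter(.data$metric %in% which_metrics, .data$node == "global") |>
    dplyr::group_by(.data$group, .data$threshold, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$threshold, y = .data$mean,
                                  colour = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "correlation threshold T", y = "group mean metric",
                  colour = "group", fill = "group") +
    ggplot2::theme_minimal()
}

#' Null distribution of a permutation test
#'
#' Histogram of the permuted t values with the observed t marked.
#'
#' @param object A `"perm_test"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot perm_test
#' @export
autoplot.perm_test <- function(object, ...) {
  d <- tibble(t = object$null_ts)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_t, colour = "red") +
    ggplot2::labs(
      x = "permuted t", y = "count",
      title = sprintf("observed t = %.2f, p = %.4g",
                      object$observed_t, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Edge-wise t map
#'
#' Tile plot of the edge-wise group-difference t statistics over the ROI x
#' ROI grid, outlining edges that survive FDR correction.
#'
#' @param edge_stats Output of [edgewise_group_test()].
#' @param atlas Atlas tibble (fixes the ROI display order).
#' @return A ggplot object.
#' @export
plot_edge_stats <- function(edge_stats, atlas = sn_cen_atlas()) {
  lv <- atlas$abbrev
  d <- dplyr::mutate(edge_stats,
                     roi_a = factor(.data$roi_a, levels = lv),
                     roi_b = factor(.data$roi_b, levels = lv))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$roi_b, y = .data$roi_a,
                                  fill = .data$t)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = dplyr::filter(d, .data$significant),
                       colour = "black", linewidth = 0.4) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = NULL, y = NULL, fill = "t") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
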