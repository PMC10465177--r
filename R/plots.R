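# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_errorbar
#'   geom_tile facet_wrap labs theme_minimal scale_fill_gradient
NULL

#' @export
ggplot2::autoplot

#' Plot a group-level metric report
#'
#' Bars of the per-group means with the original reference range drawn as a
#' band, one facet per metric.
#'
#' @param object An `organoid_group_report` from [group_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.organoid_group_report <- function(object, ...) {
  means <- object[object$statistic == "mean", ]
  rng <- object[object$statistic != "mean", ] |>
    tidyr::pivot_wider(names_from = "statistic", values_from = "value")
  ggplot(means, aes(x = .data$group, y = .data$value)) +
    geom_col(fill = "grey40") +
    ggplot2::geom_hline(data = rng, aes(yintercept = .data$range_min),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::geom_hline(data = rng, aes(yintercept = .data$range_max),
                        linetype = "dashed", colour = "steelblue") +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = NULL, y = "metric value",
         title = "Group means vs. original reference range") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a vote histogram
#'
#' @param votes Result of [votes_histogram()].
#' @return A ggplot object: images per number of positive ("real") answers.
#' @export
plot_votes <- function(votes) {
  ggplot(votes$histogram, aes(x = factor(.data$k), y = .data$n_images)) +
    geom_col(fill = "grey40") +
    labs(x = "number of experts answering \"real\"", y = "images") +
    theme_minimal()
}

#' Plot per-group error rates
#'
#' @param rates Tibble from [error_rates()] (joined with group labels).
#' @return A ggplot object.
#' @export
plot_error_rates <- function(rates) {
  ggplot(rates, aes(x = .data$group, y = .data$positive_rate)) +
    geom_col(fill = "grey40") +
    labs(x = NULL, y = "positive rate (originals: PR, synthetic: ER_G)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot decision-time summaries
#'
#' @param times Tibble from [decision_time_summary()].
#' @return A ggplot object with mean +/- sd error bars.
#' @export
plot_decision_times <- function(times) {
  key <- setdiff(names(times), c("mean_time", "sd_time", "n"))[1]
  ggplot(times, aes(x = .data[[key]], y = .data$mean_time)) +
    geom_col(fill = "grey40") +
    geom_errorbar(aes(ymin = .data$mean_time - .data$sd_time,
                      ymax = .data$mean_time + .data$sd_time), width = 0.3) +
    labs(x = NULL, y = "decision time (s)") +
    theme_minimal()
}

#' Heatmap of the best metric combinations
#'
#' @param object A `combo_correlations` tibble.
#' @param n Number of top combinations to show (default 10).
#' @param ... Unused.
#' @return A ggplot object: correlation of each top combination with NER
#'   and decision time.
#' @export
autoplot.combo_correlations <- function(object, n = 10, ...) {
  top <- top_combinations(object, n) |>
    tidyr::pivot_longer(c("pearson_ner", "pearson_time"),
                        names_to = "target", values_to = "r")
  ggplot(top, aes(x = .data$target, y = stats::reorder(.data$combination, -.data$rank),
                  fill = .data$r)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "darkgreen", limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "Pearson r") +
    theme_minimal()
}

#' Display an image or overlay matrix
#'
#' Thin raster wrapper: grayscale matrices and RGB overlay arrays plot with
#' the origin at the top-left, matching how the masks are indexed.
#'
#' @param x Matrix in \[0, 255\] or `h x w x 3` array in \[0, 1\].
#' @param ... Passed to [graphics::rasterImage()].
#' @export
show_image <- function(x, ...) {
  if (is.matrix(x)) x <- x / 255
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::rasterImage(grDevices::as.raster(x), 0, 0, 1, 1, ...)
}
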