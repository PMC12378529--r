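#' Plot a sequential glycation series
#'
#' Faceted time-series view of the four biomarkers and the two glycation
#' indices across the annual draws; a predicted row (from [track_report()])
#' is drawn as an open point.
#'
#' @param object A `glyco_series`, or a [track_report()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.glyco_series <- function(object, ...) {
  df <- as_tibble(object)
  if (!"predicted" %in% names(df)) df$predicted <- FALSE
  long <- tidyr::pivot_longer(
    dplyr::select(df, "year", "predicted", "a1c_percent", "fructosamine",
                  "ctni", "ldl", "tgi", "lgi"),
    cols = -c("year", "predicted"),
    names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$value)) +
    ggplot2::geom_line(data = function(d) d[!d$predicted, ]) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$predicted), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                name = "predicted") +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "year", y = NULL,
                  title = "Sequential biomarker and glycation-index report")
}

#' Plot index trajectories and their excess-burden area
#'
#' @param trajectories One or more [index_trajectory()] tibbles row-bound
#'   together (distinguished by `label`).
#' @param baseline Baseline index value; the shaded region above it is the
#'   excess burden integrated by [excess_burden()].
#' @return A ggplot object.
#' @examples
#' tr <- dplyr::bind_rows(
#'   index_trajectory(trajectory_preset("normal")$tgi),
#'   index_trajectory(trajectory_preset("prediabetic")$tgi))
#' plot_trajectories(tr, baseline = 1.6)
#' @export
plot_trajectories <- function(trajectories, baseline = NULL) {
  p <- ggplot2::ggplot(trajectories,
                       ggplot2::aes(x = .data$time, y = .data$index,
                                    colour = .data$label)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "years", y = toupper(trajectories$index_type[[1]]),
                  colour = NULL,
                  title = "Glycation-index trajectories",
                  subtitle = "shaded: excess above baseline (cumulative burden)")
  if (!is.null(baseline)) {
    p <- p +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = baseline,
                                        ymax = pmax(.data$index, baseline),
                                        fill = .data$label),
                           alpha = 0.2, colour = NA) +
      ggplot2::geom_hline(yintercept = baseline, linetype = "dashed") +
      ggplot2::labs(fill = NULL)
  }
  p
}
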