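#' Plot imbalance calls
#'
#' Reference-allele fraction against total read depth, colored by imbalance
#' status; the dashed line marks the balanced expectation of 0.5.
#'
#' @param object An `imbalance_calls` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.imbalance_calls <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(n = .data$n1 + .data$n2,
                  frac = .data$n1 / pmax(.data$n, 1))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$frac,
                                   colour = .data$imbalanced)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "reads at site (n1 + n2)",
                  y = "allele-1 (genome) fraction",
                  colour = "imbalanced") +
    ggplot2::theme_minimal()
}

#' Plot a stratified evaluation
#'
#' Sensitivity and precision per stratum as a grouped bar chart.
#'
#' @param object An `evaluation_result` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evaluation_result <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("sensitivity", "precision"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
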