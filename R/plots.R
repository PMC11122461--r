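#' Plot an accuracy distribution curve
#'
#' Cumulative percentage of estimates within each threshold distance of
#' the target tone.
#'
#' @param object An [accuracy_distribution()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.accuracy_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$threshold,
                                       y = .data$accuracy)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "estimated-to-target distance threshold",
                  y = "accuracy (%)") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
}

#' Plot training curves for a fitted model
#'
#' Loss and threshold-0.5 accuracies per epoch.
#'
#' @param object A `monk_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.monk_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -"epoch",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the Monk scale anchors
#'
#' Swatches of the ten anchor colours against their indices.
#'
#' @param scale A [monk_scale()].
#' @return A ggplot.
#' @export
plot_monk_scale <- function(scale = monk_scale()) {
  df <- as_tibble(scale)
  df$hex <- grDevices::rgb(df$r, df$g, df$b, maxColorValue = 255)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = 1,
                                   fill = .data$hex)) +
    ggplot2::geom_tile(width = 0.9, height = 0.9) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_x_continuous(breaks = 1:10) +
    ggplot2::labs(x = "Monk tone index", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot per-group LAB error from an evaluation report
#'
#' Mean +/- population-sd LAB error per skin-tone group.
#'
#' @param report A `monk_eval_report`.
#' @return A ggplot.
#' @export
plot_group_errors <- function(report) {
  tab <- filter(tidy(report), .data$scope == "tone_group",
                .data$metric %in% c("lab_mu", "lab_sigma"))
  wide <- tidyr::pivot_wider(tab, names_from = "metric",
                             values_from = "value")
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$group, y = .data$lab_mu)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(.data$lab_mu - .data$lab_sigma, 0),
      ymax = .data$lab_mu + .data$lab_sigma), width = 0.2) +
    ggplot2::labs(x = NULL, y = "LAB error (mu +/- sigma)") +
    ggplot2::theme_minimal()
}
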