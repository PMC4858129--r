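# ggplot2 layers over the result objects. All figures are derived from
# the exported data tables; nothing here is needed for the statistics.

#' Plot a Kaplan-Meier estimate
#'
#' Step curves of breast-cancer-specific survival, one per group.
#'
#' @param object An `npi_km` from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.npi_km <- function(object, ...) {
  anchor <- object$curve |>
    dplyr::distinct(.data$group) |>
    mutate(time = 0, survival = 1)
  dat <- bind_rows(anchor,
                   select(object$curve, "group", "time", "survival")) |>
    arrange(.data$group, .data$time)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$survival,
                                    colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years", y = "BCSS probability", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a class or group distribution
#'
#' @param dist A distribution tibble (e.g. from [class_distribution()] or
#'   a report's `group_distribution`) with a label column and `n`.
#' @param label Name of the label column (default `"class"`).
#' @return A ggplot bar chart.
#' @export
plot_distribution <- function(dist, label = "class") {
  dist <- mutate(dist, .lab = factor(.data[[label]],
                                     levels = unique(.data[[label]])))
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$.lab, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Patients") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot report association strengths
#'
#' @param report An `npi_report`.
#' @return A ggplot of Cramer's V per clinicopathological variable.
#' @export
plot_associations <- function(report) {
  if (!inherits(report, "npi_report")) abort("`report` must be an npi_report.")
  ggplot2::ggplot(report$associations,
                  ggplot2::aes(x = .data$variable, y = .data$cramers_v)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Cramer's V") +
    ggplot2::theme_minimal()
}
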