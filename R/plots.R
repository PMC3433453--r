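# ggplot2 displays for simulation and sensitivity results.

#' Plot a simulation's emission intervals
#'
#' Point-range plot of the median and nonparametric interval per ecosystem,
#' with the aggregated total.
#'
#' @param object A `bc_sim`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bc_sim
#' @export
autoplot.bc_sim <- function(object, ...) {
  dat <- tidy(object) |>
    dplyr::mutate(ecosystem = factor(.data$ecosystem, levels = .data$ecosystem))
  ggplot2::ggplot(
    dat,
    ggplot2::aes(
      x = .data$ecosystem, y = .data$median,
      ymin = .data$lower, ymax = .data$upper
    )
  ) +
    ggplot2::geom_pointrange() +
    ggplot2::labs(
      x = NULL,
      y = expression("Emissions (Pg " * CO[2] * " " * yr^-1 * ")"),
      title = "Annual blue carbon emissions",
      subtitle = sprintf(
        "Median and 90%% nonparametric interval, %s iterations",
        format(object$config$n_iterations, big.mark = ",")
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot sensitivity contributions
#'
#' Horizontal bars of each input factor's percent contribution to total
#' emissions uncertainty.
#'
#' @param object A `bc_sensitivity`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bc_sensitivity
#' @export
autoplot.bc_sensitivity <- function(object, ...) {
  dat <- tibble::as_tibble(object) |>
    dplyr::mutate(
      label = paste(.data$ecosystem, .data$factor),
      label = stats::reorder(.data$label, .data$contribution)
    )
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$contribution, y = .data$label)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "Contribution to total uncertainty (%)", y = NULL,
      title = "Input-factor uncertainty contributions",
      subtitle = sprintf("Residual (unexplained) share: %.1f%%", attr(object, "residual"))
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
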