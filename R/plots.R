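#' Plot the distribution of a Monte Carlo risk output
#'
#' Histogram of the per-iteration HQ (or CDI) draws with the risk threshold
#' marked: HQ = 1, or the CDI reference dose.
#'
#' @param object A `risk_result`.
#' @param output `"HQ"` (default) or `"CDI"`.
#' @param cdi_reference Reference line for CDI plots (default 0.06 mg/kg/day).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot risk_result
#' @export
autoplot.risk_result <- function(object, output = c("HQ", "CDI"),
                                 cdi_reference = 0.06, ...) {
  output <- match.arg(output)
  ref <- if (output == "HQ") 1 else cdi_reference
  df <- tibble::tibble(value = object$draws[[output]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 60, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = ref, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(
      x = if (output == "HQ") "Hazard quotient" else "CDI (mg/kg/day)",
      y = "Iterations",
      title = paste0(object$scenario$product_type, " tea, ",
                     object$scenario$age_group),
      subtitle = sprintf("%d iterations, seed %d; dashed line: %s",
                         object$n_iterations, object$seed,
                         if (output == "HQ") "HQ = 1" else
                           paste0("RfD = ", ref, " mg/kg/day"))
    ) +
    ggplot2::theme_minimal()
}

#' Tornado plot of a sensitivity report
#'
#' Horizontal bars of signed contribution-to-variance percentages, largest
#' absolute contribution on top -- the conventional tornado display.
#'
#' @param object A `sensitivity_report` from [contribution_to_variance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sensitivity_report
#' @export
autoplot.sensitivity_report <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(.data$varies) |>
    dplyr::mutate(parameter = stats::reorder(.data$parameter,
                                             abs(.data$contribution)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$contribution, y = .data$parameter,
                                   fill = .data$contribution > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "firebrick")) +
    ggplot2::labs(x = "Contribution to variance (%)", y = NULL,
                  title = paste0("Sensitivity of ",
                                 attr(object, "output") %||% "output")) +
    ggplot2::theme_minimal()
}

#' Plot type-level concentration summaries across brewing times
#'
#' Mean infusible fluoride per product type against brewing time with +/- 1
#' SD error bars, the summary view of a concentration table.
#'
#' @param summaries A tibble with columns `product_type`, `brew_time_min`,
#'   `mean_mg_per_L`, `sd_mg_per_L` (see [paper_table2_summaries()] or
#'   [summarize_infusion_study()]).
#' @return A ggplot object.
#' @export
plot_infusion_summary <- function(summaries) {
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$brew_time_min, y = .data$mean_mg_per_L,
                               colour = .data$product_type,
                               group = .data$product_type)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean_mg_per_L - .data$sd_mg_per_L, 0),
                   ymax = .data$mean_mg_per_L + .data$sd_mg_per_L),
      width = 0.6, alpha = 0.6
    ) +
    ggplot2::labs(x = "Brewing time (min)", y = "Infusible fluoride (mg/L)",
                  colour = "Product type") +
    ggplot2::theme_minimal()
}
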