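#' Contribution-to-variance sensitivity analysis
#'
#' Attributes output variability to each stochastic input using the method of
#' the commercial Monte Carlo packages this analysis emulates: for each
#' varying input compute the Spearman rank correlation `r_i` between its
#' draws and the output draws, then report the signed, normalized squared
#' correlation `sign(r_i) * r_i^2 / sum_j r_j^2 * 100` as a percentage.
#' Absolute contributions always sum to 100 when at least one input varies.
#' Zero-variance (point-mass) inputs are excluded from the normalization and
#' reported with contribution 0 and `varies = FALSE`.
#'
#' `contribution_to_variance()` is generic: apply it to a `risk_result` (the
#' five sampled dose inputs against CDI or HQ) or to any data frame of input
#' draws paired with an output vector.
#'
#' @param x A `risk_result` from [run_monte_carlo()], or a data frame whose
#'   columns are input draws.
#' @param output For a `risk_result`: `"HQ"` (default) or `"CDI"`. For a data
#'   frame: a numeric vector of output draws, same length as the columns.
#' @param ... Passed between methods.
#' @return A `sensitivity_report`: a tibble ordered by `|contribution|` with
#'   columns `parameter`, `rho` (Spearman correlation, `NA` for constant
#'   inputs), `contribution` (signed percent), `varies`; the output name is
#'   attached as attribute `"output"`.
#' @examples
#' sc <- closed_form_scenario("all_lognormal")$scenario
#' contribution_to_variance(run_monte_carlo(sc, 2000, seed = 7))
#' @export
contribution_to_variance <- function(x, output, ...) {
  UseMethod("contribution_to_variance")
}

#' @rdname contribution_to_variance
#' @export
contribution_to_variance.risk_result <- function(x, output = c("HQ", "CDI"),
                                                 ...) {
  output <- match.arg(output)
  inputs <- x$draws[c("C", "DI", "EF", "ED", "BW")]
  out <- ctv_table(inputs, x$draws[[output]])
  attr(out, "output") <- output
  out
}

#' @rdname contribution_to_variance
#' @export
contribution_to_variance.data.frame <- function(x, output, ...) {
  if (!is.numeric(output) || length(output) != nrow(x)) {
    rlang::abort("`output` must be a numeric vector with one value per row of `x`.",
                 class = "fluorisk_error_domain")
  }
  out <- ctv_table(x, output)
  attr(out, "output") <- "output"
  out
}

ctv_table <- function(inputs, output) {
  if (length(output) < 2) {
    rlang::abort("sensitivity analysis needs at least 2 iterations.",
                 class = "fluorisk_error_insufficient_data")
  }
  varies <- vapply(inputs, function(v) stats::sd(v) > 0, logical(1))
  if (!any(varies)) {
    rlang::abort("all inputs are constant: nothing to attribute variance to.",
                 class = "fluorisk_error_degenerate")
  }
  if (stats::sd(output) == 0) {
    rlang::abort("output has zero variance: contributions are undefined.",
                 class = "fluorisk_error_degenerate")
  }
  rnk_out <- rank(output, ties.method = "average")
  rho <- vapply(names(inputs), function(nm) {
    if (!varies[[nm]]) return(NA_real_)
    stats::cor(rank(inputs[[nm]], ties.method = "average"), rnk_out)
  }, numeric(1))
  denom <- sum(rho[varies]^2)
  contribution <- ifelse(varies, sign(rho) * rho^2 / denom * 100, 0)
  contribution[is.na(contribution)] <- 0
  out <- tibble::tibble(
    parameter = names(inputs),
    rho = unname(rho),
    contribution = unname(contribution),
    varies = unname(varies)
  )
  out <- dplyr::arrange(out, dplyr::desc(abs(.data$contribution)))
  class(out) <- c("sensitivity_report", class(out))
  out
}

#' Cross-scenario sensitivity ranges
#'
#' Condenses several sensitivity reports (e.g. one per product type within an
#' age group) into the range form risk studies report: for each parameter,
#' the minimum and maximum signed contribution across scenarios and a
#' `"low%-high%"` label, ordered by the largest absolute contribution.
#'
#' @param reports A list of `sensitivity_report` objects (a single report is
#'   accepted and wrapped).
#' @return A tibble: `parameter`, `min_contribution`, `max_contribution`,
#'   `range_label`, `max_abs`.
#' @export
sensitivity_narrative <- function(reports) {
  if (inherits(reports, "sensitivity_report")) reports <- list(reports)
  if (length(reports) == 0) {
    rlang::abort("need at least one sensitivity report.",
                 class = "fluorisk_error_empty")
  }
  dplyr::bind_rows(lapply(reports, as.data.frame)) |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      min_contribution = min(.data$contribution),
      max_contribution = max(.data$contribution),
      max_abs = max(abs(.data$contribution)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      range_label = sprintf("%.1f%%–%.1f%%", .data$min_contribution,
                            .data$max_contribution)
    ) |>
    dplyr::arrange(dplyr::desc(.data$max_abs)) |>
    dplyr::select("parameter", "min_contribution", "max_contribution",
                  "range_label", "max_abs")
}
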