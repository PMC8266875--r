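#' Synthetic study design
#'
#' Describes a study-shaped infusion experiment: per product type and brewing
#' time, the number of brands, the type-level mean concentration and the
#' between-brand SD; plus the replicate count per brand x time cell and the
#' within-brand replicate coefficient of variation. The default design is the
#' published study layout -- 16 brands (5 black, 3 green, 3 oolong, 3 herbal,
#' 2 white), triplicate measurements at 5, 10 and 20 min -- with type-level
#' means/SDs taken from [paper_table2_summaries()]. The published type-level
#' SDs are treated as between-brand SDs; within-brand replicate noise
#' defaults to a 5% CV, consistent with the small replicate SDs the study
#' reports at brand level.
#'
#' @param summaries Type-level summaries (columns as in
#'   [paper_table2_summaries()]) giving brand counts, means and between-brand
#'   SDs per type and brewing time.
#' @param replicates Replicates per brand x time cell (default 3).
#' @param replicate_cv Within-brand replicate coefficient of variation
#'   (default 0.05).
#' @param leaf_state `"uncrushed"` (default) or `"crushed"`.
#' @return A `study_design` object.
#' @export
study_design <- function(summaries = paper_table2_summaries(), replicates = 3,
                         replicate_cv = 0.05, leaf_state = "uncrushed") {
  required <- c("product_type", "brew_time_min", "n_brands", "mean_mg_per_L",
                "sd_mg_per_L")
  missing <- setdiff(required, names(summaries))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("summaries missing column(s): ", paste(missing, collapse = ", ")),
      class = "fluorisk_error_schema"
    )
  }
  if (any(summaries$n_brands < 1)) {
    rlang::abort("brand counts must be >= 1.", class = "fluorisk_error_validation")
  }
  if (any(summaries$sd_mg_per_L < 0) || replicate_cv < 0) {
    rlang::abort("SDs and replicate_cv must be >= 0.",
                 class = "fluorisk_error_validation")
  }
  if (replicates < 1 || replicates != floor(replicates)) {
    rlang::abort("`replicates` must be a positive integer.",
                 class = "fluorisk_error_validation")
  }
  leaf_state <- match.arg(leaf_state, leaf_states)
  structure(
    list(summaries = tibble::as_tibble(summaries),
         replicates = as.integer(replicates),
         replicate_cv = replicate_cv, leaf_state = leaf_state),
    class = "study_design"
  )
}

#' Generate a study-shaped synthetic infusion dataset
#'
#' Simulates brand-level fluoride measurements under a [study_design()].
#' Brand means are drawn from a normal distribution centred on the type-level
#' mean with the between-brand SD, truncated at zero (concentrations are
#' physical); a single uniform quantile per brand is shared across brewing
#' times so a brand that is fluoride-rich at 5 min stays fluoride-rich at 20
#' min. Replicate values add within-brand noise (normal, CV of the brand
#' mean, truncated at zero). With all SDs and the CV at zero every value
#' equals its type mean exactly. Generation is deterministic under `seed`,
#' with independent substreams per product type.
#'
#' @param design A [study_design()].
#' @param seed Integer seed.
#' @return A validated long-format infusion tibble (see [infusion-data]).
#' @examples
#' synth <- generate_infusion_study(study_design(), seed = 1)
#' dplyr::count(synth, product_type)
#' @export
generate_infusion_study <- function(design, seed = 1) {
  if (!inherits(design, "study_design")) {
    rlang::abort("`design` must be a study_design.", class = "fluorisk_error_spec")
  }
  s <- design$summaries
  types <- unique(s$product_type)
  rows <- purrr::map_dfr(types, function(ty) {
    st <- dplyr::filter(s, .data$product_type == ty)
    n_brands <- st$n_brands[1]
    # one latent quantile per brand, shared across brew times
    u <- dist_sample(dist_uniform(0, 1), n_brands,
                     seed = derive_seed(seed, paste0("brand_", ty)))
    purrr::map_dfr(seq_len(nrow(st)), function(i) {
      m <- st$mean_mg_per_L[i]; sd_b <- st$sd_mg_per_L[i]
      t_min <- st$brew_time_min[i]
      brand_means <- if (sd_b == 0) {
        rep(m, n_brands)
      } else {
        dist_quantile(dist_normal(m, sd_b, truncate = c(0, Inf)), u)
      }
      purrr::map_dfr(seq_len(n_brands), function(b) {
        bm <- brand_means[b]
        reps <- if (design$replicate_cv == 0 || bm == 0) {
          rep(bm, design$replicates)
        } else {
          dist_sample(
            dist_normal(bm, design$replicate_cv * bm, truncate = c(0, Inf)),
            design$replicates,
            seed = derive_seed(seed, paste(ty, t_min, b, sep = "_"))
          )
        }
        tibble::tibble(
          product_type = ty,
          brand_id = paste0(ty, "_", b),
          brew_time_min = t_min,
          replicate = seq_len(design$replicates),
          fluoride_mg_per_L = reps,
          censored = FALSE,
          leaf_state = design$leaf_state
        )
      })
    })
  })
  validate_infusion_data(rows)
}

#' Summarize an infusion dataset to type-level statistics
#'
#' Collapses brand-level replicate measurements to the published summary
#' form: per product type and brewing time, the number of brands and the mean
#' and sample SD of the per-brand mean concentrations.
#'
#' @param data A validated infusion tibble.
#' @return A tibble with columns `product_type`, `brew_time_min`, `n_brands`,
#'   `mean_mg_per_L`, `sd_mg_per_L`.
#' @export
summarize_infusion_study <- function(data) {
  data <- validate_infusion_data(data)
  data |>
    dplyr::group_by(.data$product_type, .data$brew_time_min, .data$brand_id) |>
    dplyr::summarise(brand_mean = mean(.data$fluoride_mg_per_L),
                     .groups = "drop") |>
    dplyr::group_by(.data$product_type, .data$brew_time_min) |>
    dplyr::summarise(
      n_brands = dplyr::n(),
      mean_mg_per_L = mean(.data$brand_mean),
      sd_mg_per_L = if (dplyr::n() > 1) stats::sd(.data$brand_mean) else 0,
      .groups = "drop"
    )
}

#' Known-truth exposure scenarios with closed-form CDI distributions
#'
#' Builds a scenario whose CDI distribution is known exactly, for
#' parameter-recovery and Monte Carlo correctness checks:
#'
#' * `"all_point"` -- every input a point mass (C = 2.54 mg/L, DI = 1 L/day,
#'   EF = 365 d/yr, ED = 10 yr, BW = 30 kg, AT = ED x 365); CDI is the point
#'   mass `2.54 / 30`.
#' * `"lognormal_C"` -- C lognormal(`meanlog` 0, `sdlog` 0.5), the rest point
#'   masses with multiplier `k = DI * EF / (365 * BW)`; CDI is
#'   lognormal(`log k`, 0.5).
#' * `"all_lognormal"` -- C, DI, EF, BW lognormal (ED lognormal too, but it
#'   cancels under the `ED x 365` averaging-time rule); log CDI is normal
#'   with mean `meanlog_C + meanlog_DI + meanlog_EF - meanlog_BW - log(365)`
#'   and variance the sum of the four squared sdlogs, BW entering the mean
#'   with negative sign.
#'
#' @param kind `"all_point"`, `"lognormal_C"` or `"all_lognormal"`.
#' @return A list: `scenario` (an [exposure_scenario()] for children, RfD
#'   0.06) and `cdi_dist` (the exact CDI distribution as a [dist_spec]).
#' @export
closed_form_scenario <- function(kind = c("all_point", "lognormal_C",
                                          "all_lognormal")) {
  kind <- match.arg(kind)
  if (kind == "all_point") {
    sc <- exposure_scenario(
      "children", "black",
      C = dist_point(2.54), DI = dist_point(1), EF = dist_point(365),
      ED = dist_point(10), BW = dist_point(30)
    )
    return(list(scenario = sc, cdi_dist = dist_point(2.54 / 30)))
  }
  if (kind == "lognormal_C") {
    DI <- 0.5; EF <- 365; BW <- 25
    k <- DI * EF / (365 * BW)
    sc <- exposure_scenario(
      "children", "black",
      C = dist_lognormal(0, 0.5), DI = dist_point(DI), EF = dist_point(EF),
      ED = dist_point(6), BW = dist_point(BW)
    )
    return(list(scenario = sc, cdi_dist = dist_lognormal(log(k), 0.5)))
  }
  # all_lognormal: log-scale parameters chosen to resemble a child tea-drinker
  mu <- c(C = log(2.0), DI = log(0.3), EF = log(330), BW = log(22))
  sg <- c(C = 0.4, DI = 0.3, EF = 0.1, BW = 0.2)
  sc <- exposure_scenario(
    "children", "black",
    C = dist_lognormal(mu[["C"]], sg[["C"]]),
    DI = dist_lognormal(mu[["DI"]], sg[["DI"]]),
    EF = dist_lognormal(mu[["EF"]], sg[["EF"]]),
    ED = dist_lognormal(log(6), 0.3),
    BW = dist_lognormal(mu[["BW"]], sg[["BW"]])
  )
  meanlog <- mu[["C"]] + mu[["DI"]] + mu[["EF"]] - mu[["BW"]] - log(365)
  sdlog <- sqrt(sg[["C"]]^2 + sg[["DI"]]^2 + sg[["EF"]]^2 + sg[["BW"]]^2)
  list(scenario = sc, cdi_dist = dist_lognormal(meanlog, sdlog))
}
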