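#' Infusion measurement data
#'
#' Brand-level fluoride measurements from tea and herbal infusions are kept in
#' a long-format tibble with one row per replicate:
#'
#' * `product_type` -- one of `"black"`, `"green"`, `"oolong"`, `"herbal"`,
#'   `"white"`
#' * `brand_id` -- brand identifier (character)
#' * `brew_time_min` -- brewing time in minutes (positive; the study design
#'   uses 5, 10 and 20)
#' * `replicate` -- positive integer replicate index
#' * `fluoride_mg_per_L` -- measured fluoride concentration (mg/L); for
#'   censored rows this holds the detection limit
#' * `censored` -- logical, `TRUE` when the measurement fell below the
#'   detection limit ("<DL"); censored values are never silently substituted,
#'   the substitution policy is chosen at analysis time
#'   (see [spearman_censored()])
#' * `leaf_state` -- `"uncrushed"` or `"crushed"`
#'
#' @name infusion-data
NULL

product_types <- c("black", "green", "oolong", "herbal", "white")
leaf_states <- c("uncrushed", "crushed")
water_types <- c("distilled", "ultrapure", "RO", "tap", "bottled", "bottled_mineral")

infusion_cols <- c("product_type", "brand_id", "brew_time_min", "replicate",
                   "fluoride_mg_per_L", "censored", "leaf_state")

#' Validate an infusion dataset
#'
#' Checks the long-format schema described in [infusion-data]: required
#' columns, enum levels, non-negative uncensored concentrations, positive
#' brew times and replicate indices. Errors name the offending column or row.
#'
#' @param data A data frame of infusion measurements.
#' @return The validated data as a tibble, invisibly usable in a pipe.
#' @export
validate_infusion_data <- function(data) {
  missing <- setdiff(infusion_cols, names(data))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("missing required column(s): ", paste(missing, collapse = ", ")),
      class = "fluorisk_error_schema"
    )
  }
  extra <- setdiff(names(data), infusion_cols)
  if (length(extra) > 0) {
    rlang::abort(
      paste0("unexpected column(s): ", paste(extra, collapse = ", ")),
      class = "fluorisk_error_schema"
    )
  }
  data <- tibble::as_tibble(data)
  row_fail <- function(cond, what) {
    if (any(cond, na.rm = TRUE) || anyNA(cond)) {
      rows <- which(cond | is.na(cond))
      rlang::abort(
        paste0(what, " (row ", paste(utils::head(rows, 5), collapse = ", "),
               if (length(rows) > 5) ", ..." else "", ")"),
        class = "fluorisk_error_validation"
      )
    }
  }
  row_fail(!data$product_type %in% product_types,
           "product_type must be one of black/green/oolong/herbal/white")
  row_fail(!data$leaf_state %in% leaf_states,
           "leaf_state must be uncrushed or crushed")
  row_fail(!is.finite(data$brew_time_min) | data$brew_time_min <= 0,
           "brew_time_min must be a positive number")
  row_fail(!is.finite(data$replicate) | data$replicate < 1 |
             data$replicate != floor(data$replicate),
           "replicate must be a positive integer")
  row_fail(!is.logical(data$censored) | is.na(data$censored),
           "censored must be TRUE/FALSE")
  row_fail(!is.finite(data$fluoride_mg_per_L) | data$fluoride_mg_per_L < 0,
           "fluoride_mg_per_L must be a non-negative number")
  data
}

#' Read and write infusion measurement CSV files
#'
#' The CSV schema is long format, comma separated, UTF-8, one row per
#' replicate, with the columns of [infusion-data] except `censored`: censoring
#' is encoded in the `fluoride_mg_per_L` column itself as the literal text
#' `"<DL"`. On reading, censored entries get `fluoride_mg_per_L =
#' detection_limit` and `censored = TRUE`; writing restores the `"<DL"`
#' marker, so write-then-read is the identity on any valid dataset.
#'
#' @param path Path to a CSV file.
#' @param detection_limit Assay detection limit in mg/L substituted as the
#'   carried value for censored rows (default 0.02).
#' @param data An infusion tibble as returned by [read_infusion_csv()] or
#'   [generate_infusion_study()].
#' @return `read_infusion_csv()` returns a validated tibble;
#'   `write_infusion_csv()` returns `data` invisibly.
#' @export
read_infusion_csv <- function(path, detection_limit = 0.02) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "fluorisk_error_io")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  expected <- setdiff(infusion_cols, "censored")
  missing <- setdiff(expected, names(raw))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("missing required column(s): ", paste(missing, collapse = ", ")),
      class = "fluorisk_error_schema"
    )
  }
  extra <- setdiff(names(raw), expected)
  if (length(extra) > 0) {
    rlang::abort(
      paste0("unexpected column(s): ", paste(extra, collapse = ", ")),
      class = "fluorisk_error_schema"
    )
  }
  censored <- trimws(raw$fluoride_mg_per_L) == "<DL"
  fl <- suppressWarnings(as.numeric(raw$fluoride_mg_per_L))
  fl[censored] <- detection_limit
  bad <- which(!censored & (is.na(fl)))
  if (length(bad) > 0) {
    rlang::abort(
      paste0("unparseable fluoride_mg_per_L value (row ",
             paste(utils::head(bad, 5), collapse = ", "), ")"),
      class = "fluorisk_error_validation"
    )
  }
  out <- tibble::tibble(
    product_type = raw$product_type,
    brand_id = raw$brand_id,
    brew_time_min = as.numeric(raw$brew_time_min),
    replicate = as.numeric(raw$replicate),
    fluoride_mg_per_L = fl,
    censored = censored,
    leaf_state = raw$leaf_state
  )
  validate_infusion_data(out)
}

#' @rdname read_infusion_csv
#' @export
write_infusion_csv <- function(data, path) {
  data <- validate_infusion_data(data)
  out <- data |>
    dplyr::mutate(
      fluoride_mg_per_L = ifelse(.data$censored, "<DL",
                                 format(.data$fluoride_mg_per_L, digits = 15,
                                        trim = TRUE, scientific = FALSE))
    ) |>
    dplyr::select(-"censored")
  readr::write_csv(out, path, progress = FALSE)
  invisible(data)
}

#' Per-type fluoride concentration summaries from the source study
#'
#' Mean and standard deviation of infusible fluoride (mg/L) for each product
#' type at each brewing time, together with the number of brands per type
#' (5 black, 3 green, 3 oolong, 3 herbal, 2 white; 16 brands in all). These
#' type-level summaries are the published form of the study data -- the
#' underlying brand-level values are not deposited -- and they seed both the
#' synthetic-data generator defaults and the concentration fitting step.
#'
#' @return A tibble with columns `product_type`, `brew_time_min`, `n_brands`,
#'   `mean_mg_per_L`, `sd_mg_per_L` (15 rows: 5 types x 3 times).
#' @examples
#' paper_table2_summaries() |> weighted_overall_mean(5)
#' @export
paper_table2_summaries <- function() {
  tibble::tibble(
    product_type = rep(product_types, each = 3),
    brew_time_min = rep(c(5, 10, 20), times = 5),
    n_brands = rep(c(5L, 3L, 3L, 3L, 2L), each = 3),
    mean_mg_per_L = c(
      2.54, 2.55, 2.55,   # black
      1.19, 1.45, 1.54,   # green
      0.86, 0.91, 0.99,   # oolong
      0.40, 0.36, 0.41,   # herbal
      0.21, 0.21, 0.20    # white
    ),
    sd_mg_per_L = c(
      1.10, 0.95, 0.99,
      0.22, 0.28, 0.44,
      0.35, 0.45, 0.29,
      0.35, 0.40, 0.39,
      0.04, 0.04, 0.04
    )
  )
}

#' Water chemistry profiles of the six brewing waters
#'
#' Composition of the six waters used to brew the crushed black-tea infusions:
#' pH, conductivity, fluoride, dissolved organic carbon and major ions.
#' Fluoride in distilled, ultrapure and RO water fell below the assay
#' detection limit of 0.02 mg/L and is carried censored (`fluoride_censored =
#' TRUE` with the detection limit as the value), never silently substituted.
#' Ion values reported as not detected are `NA`.
#'
#' @return A tibble with one row per water type.
#' @export
paper_water_profiles <- function() {
  tibble::tibble(
    water_type = water_types,
    pH = c(6.28, 5.94, 6.02, 7.11, 7.78, 8.02),
    conductivity_uS_cm = c(1.50, 2.50, 70, 354, 642, 551),
    fluoride_mg_per_L = c(0.02, 0.02, 0.02, 0.176, 0.534, 1.084),
    fluoride_censored = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    detection_limit = 0.02,
    DOC_mg_per_L = c(0.18, 0.30, 0.13, 2.72, 0.26, 0.20),
    sodium_mg_per_L = c(0.261, 0.280, 8.091, 138.72, 113.39, 86.55),
    potassium_mg_per_L = c(NA, 0.015, 0.458, 7.616, 1.672, 0.976),
    calcium_mg_per_L = c(NA, 0.024, 1.285, 34.379, 3.006, 10.753),
    magnesium_mg_per_L = c(0.031, 0.087, 0.547, 20.009, 0.714, 2.756),
    chloride_mg_per_L = c(0.55, 0.63, 28.85, 326.75, 21.229, 6.390),
    bromide_mg_per_L = c(NA, NA, 0.032, 0.576, 0.077, 0.050),
    nitrate_mg_per_L = c(NA, NA, 0.640, 5.144, 0.469, 0.537),
    sulfate_mg_per_L = c(0.24, 0.15, 1.74, 112.84, 39.46, 31.150),
    phosphate_mg_per_L = rep(NA_real_, 6)
  )
}

#' Mean infusible fluoride of crushed black tea by brewing water
#'
#' Mean +/- SD fluoride concentration (mg/L) of crushed black-tea infusions
#' prepared with each of the six water types, as reported in the source
#' study's water-influence analysis. Pairs with [paper_water_profiles()] for
#' rank-correlation analyses of water chemistry against fluoride release.
#'
#' @return A tibble with columns `water_type`, `mean_mg_per_L`, `sd_mg_per_L`.
#' @export
paper_infusible_by_water <- function() {
  tibble::tibble(
    water_type = water_types,
    mean_mg_per_L = c(4.78, 4.51, 4.77, 4.86, 5.68, 5.79),
    sd_mg_per_L = c(0.08, 0.24, 0.08, 0.02, 0.29, 0.25)
  )
}
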