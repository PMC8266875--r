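#' Size-weighted overall mean across product-type groups
#'
#' Reconstructs the "all products" mean concentration at one brewing time from
#' per-type summaries: `sum(n_i * mean_i) / sum(n_i)` over the groups at that
#' time. This is the row printed beneath the per-type entries in the study's
#' concentration table.
#'
#' @param summaries A tibble of group summaries with columns `product_type`,
#'   `brew_time_min`, `n_brands`, `mean_mg_per_L`, `sd_mg_per_L` (see
#'   [paper_table2_summaries()]).
#' @param brew_time_min Brewing time (minutes) selecting the groups.
#' @return The weighted mean concentration (mg/L), a single number.
#' @examples
#' weighted_overall_mean(paper_table2_summaries(), 5) # ~1.28
#' @export
weighted_overall_mean <- function(summaries, brew_time_min) {
  g <- pick_groups(summaries, brew_time_min)
  sum(g$n_brands * g$mean_mg_per_L) / sum(g$n_brands)
}

#' Pooled sample standard deviation across groups
#'
#' Reconstructs the sample SD of the combined population from per-group
#' `(n, mean, sd)` via the within/between sum-of-squares decomposition:
#' `SS_within = sum((n_i - 1) * sd_i^2)`, `SS_between = sum(n_i * (mean_i -
#' grand_mean)^2)`, pooled SD `= sqrt((SS_within + SS_between) / (N - 1))`
#' with `N = sum(n_i)`. Group SDs must be sample (n-1 denominator) SDs.
#'
#' @inheritParams weighted_overall_mean
#' @return The pooled sample SD (mg/L), a single number.
#' @examples
#' pooled_sd(paper_table2_summaries(), 5) # ~1.11
#' @export
pooled_sd <- function(summaries, brew_time_min) {
  g <- pick_groups(summaries, brew_time_min)
  n_tot <- sum(g$n_brands)
  if (n_tot < 2) {
    rlang::abort("pooled SD needs a combined group size of at least 2.",
                 class = "fluorisk_error_insufficient_data")
  }
  if (nrow(g) == 1) return(g$sd_mg_per_L)
  gm <- sum(g$n_brands * g$mean_mg_per_L) / n_tot
  ss_within <- sum((g$n_brands - 1) * g$sd_mg_per_L^2)
  ss_between <- sum(g$n_brands * (g$mean_mg_per_L - gm)^2)
  sqrt((ss_within + ss_between) / (n_tot - 1))
}

pick_groups <- function(summaries, brew_time_min) {
  required <- c("product_type", "brew_time_min", "n_brands", "mean_mg_per_L",
                "sd_mg_per_L")
  missing <- setdiff(required, names(summaries))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("summaries missing column(s): ", paste(missing, collapse = ", ")),
      class = "fluorisk_error_schema"
    )
  }
  g <- dplyr::filter(summaries, .data$brew_time_min == !!brew_time_min)
  if (nrow(g) == 0) {
    rlang::abort(
      paste0("no groups at brew time ", brew_time_min, " min."),
      class = "fluorisk_error_empty"
    )
  }
  if (any(g$n_brands < 1)) {
    rlang::abort("all group sizes must be >= 1.", class = "fluorisk_error_validation")
  }
  g
}

#' Overall concentration summary across brewing times
#'
#' Convenience wrapper producing the "all products" row of a concentration
#' table: size-weighted mean and pooled SD at every brewing time present.
#'
#' @inheritParams weighted_overall_mean
#' @return A tibble with columns `brew_time_min`, `n_brands`, `mean_mg_per_L`,
#'   `sd_mg_per_L`.
#' @export
overall_summary <- function(summaries) {
  times <- sort(unique(summaries$brew_time_min))
  purrr::map_dfr(times, function(t) {
    g <- pick_groups(summaries, t)
    tibble::tibble(
      brew_time_min = t,
      n_brands = sum(g$n_brands),
      mean_mg_per_L = weighted_overall_mean(summaries, t),
      sd_mg_per_L = pooled_sd(summaries, t)
    )
  })
}

#' Shapiro-Wilk normality check
#'
#' The normality gate used before choosing nonparametric pairwise tests: small
#' infusion datasets rarely pass, motivating rank-based comparisons
#' downstream.
#'
#' @param x Numeric vector, `3 <= length(x) <= 5000`.
#' @return A one-row tibble: `statistic` (W), `p_value`, `method`, `n`.
#' @export
normality_check <- function(x) {
  x <- as.numeric(x)
  x <- x[!is.na(x)]
  if (length(x) < 3) {
    rlang::abort("Shapiro-Wilk needs at least 3 values.",
                 class = "fluorisk_error_insufficient_data")
  }
  if (stats::sd(x) == 0) {
    rlang::abort(
      "all values identical: the normality statistic is undefined for a zero-variance sample.",
      class = "fluorisk_error_degenerate"
    )
  }
  sw <- stats::shapiro.test(x)
  tibble::tibble(
    statistic = unname(sw$statistic),
    p_value = sw$p.value,
    method = "Shapiro-Wilk",
    n = length(x)
  )
}

#' Mann-Whitney U comparison of two groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. The exact null
#' distribution is used when the combined sample size is at most
#' `exact_max_n` and there are no ties across groups -- the regime of the
#' study's small brand groups (2-5 brands per type) -- otherwise the normal
#' approximation with tie correction (no continuity correction, the common
#' statistical-package convention, so identical samples give p = 1 exactly)
#' is used; the `method` label records which path ran. The reported `statistic` is U for
#' the first group (number of pairs `(a_i, b_j)` with `a_i > b_j`, ties
#' counted one half), so `U = 0` when every `a` value is below every `b`
#' value; the symmetric convention `n_a * n_b - U` is the U of the second
#' group.
#'
#' @param a,b Numeric vectors, both nonempty.
#' @param exact_max_n Largest combined sample size for which the exact null
#'   distribution is used (default 20).
#' @return A one-row tibble: `statistic` (U), `p_value`, `method`, `n_a`,
#'   `n_b`, `alternative`.
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
#' @export
compare_groups <- function(a, b, exact_max_n = 20) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) {
    rlang::abort("both groups must be nonempty.", class = "fluorisk_error_empty")
  }
  if (stats::sd(c(a, b)) == 0) {
    # all pooled values identical: the groups are indistinguishable
    return(tibble::tibble(
      statistic = length(a) * length(b) / 2, p_value = 1,
      method = "Mann-Whitney U (degenerate: all values tied)",
      n_a = length(a), n_b = length(b), alternative = "two.sided"
    ))
  }
  has_ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- (length(a) + length(b)) <= exact_max_n && !has_ties
  # no continuity correction on the approximate path: identical samples then
  # give z = 0 and p = 1 exactly
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = use_exact,
                       correct = FALSE)
  )
  tibble::tibble(
    statistic = unname(wt$statistic),
    p_value = min(wt$p.value, 1),
    method = if (use_exact) "Mann-Whitney U (exact)"
             else "Mann-Whitney U (normal approximation, tie-corrected)",
    n_a = length(a),
    n_b = length(b),
    alternative = "two.sided"
  )
}

#' All pairwise group comparisons for an infusion dataset
#'
#' Runs [compare_groups()] on per-brand mean concentrations for every pair of
#' product types at one brewing time, the tidy form of the study's pairwise
#' concentration contrasts. Optionally applies a Holm adjustment (the source
#' analysis applied none, so the default is unadjusted).
#'
#' @param data A validated infusion tibble (see [infusion-data]).
#' @param brew_time_min Brewing time to compare at (default 5).
#' @param adjust Multiple-testing adjustment: `"none"` (default) or `"holm"`.
#' @return A tibble with one row per type pair: `type_a`, `type_b`,
#'   `statistic`, `p_value`, `method`, `n_a`, `n_b`.
#' @export
pairwise_comparisons <- function(data, brew_time_min = 5,
                                 adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  data <- validate_infusion_data(data)
  means <- data |>
    dplyr::filter(.data$brew_time_min == !!brew_time_min) |>
    dplyr::group_by(.data$product_type, .data$brand_id) |>
    dplyr::summarise(value = mean(.data$fluoride_mg_per_L), .groups = "drop")
  types <- intersect(product_types, unique(means$product_type))
  if (length(types) < 2) {
    rlang::abort("need at least two product types to compare.",
                 class = "fluorisk_error_insufficient_data")
  }
  pairs <- utils::combn(types, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    ta <- pairs[1, k]; tb <- pairs[2, k]
    res <- compare_groups(means$value[means$product_type == ta],
                          means$value[means$product_type == tb])
    dplyr::bind_cols(tibble::tibble(type_a = ta, type_b = tb), res)
  })
  if (adjust == "holm") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "holm")
  }
  out
}

#' Spearman rank correlation with censored values
#'
#' Spearman's rho computed as the Pearson correlation of average ranks, with
#' an explicit policy for values censored below a detection limit:
#'
#' * `"substitute_dl"` (default) -- censored entries take the detection limit
#'   as their value, creating ties at the limit that average ranks share;
#'   this is the policy under which the water-chemistry correlations of the
#'   source study are reproduced
#' * `"substitute_half_dl"` -- censored entries take half the detection limit
#' * `"drop_censored"` -- censored pairs are removed (at least 3 pairs must
#'   remain)
#'
#' The p-value uses the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on
#' `n - 2` degrees of freedom (two-sided), which accommodates ties; for
#' `|rho| = 1` the p-value is reported as the exact permutation tail
#' `2 / n!`.
#'
#' @param x Numeric vector, possibly censored (censored entries' stored value
#'   is ignored and replaced per the policy).
#' @param y Numeric vector, same length as `x`, uncensored.
#' @param censored Logical vector marking censored entries of `x` (default
#'   none).
#' @param detection_limit Detection limit used by the substitution policies
#'   (default 0.02 mg/L).
#' @param policy Censoring policy, see above.
#' @return A one-row tibble: `rho`, `p_value`, `n`, `method`, `tie_policy`,
#'   `censor_policy`.
#' @examples
#' w <- paper_water_profiles()
#' spearman_censored(w$fluoride_mg_per_L, paper_infusible_by_water()$mean_mg_per_L,
#'                   censored = w$fluoride_censored) # rho ~ 0.941
#' @export
spearman_censored <- function(x, y, censored = NULL, detection_limit = 0.02,
                              policy = c("substitute_dl", "substitute_half_dl",
                                         "drop_censored")) {
  policy <- match.arg(policy)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) {
    rlang::abort("`x` and `y` must have the same length.",
                 class = "fluorisk_error_domain")
  }
  if (is.null(censored)) censored <- rep(FALSE, length(x))
  if (policy == "drop_censored") {
    keep <- !censored
    x <- x[keep]; y <- y[keep]
  } else {
    x[censored] <- if (policy == "substitute_dl") detection_limit
                   else detection_limit / 2
  }
  n <- length(x)
  if (n < 3) {
    rlang::abort("fewer than 3 pairs remain after applying the censoring policy.",
                 class = "fluorisk_error_insufficient_data")
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1 - 1e-12) {
    min(1, 2 / factorial(n))
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(
    rho = rho,
    p_value = p,
    n = n,
    method = "Spearman rank correlation (t approximation)",
    tie_policy = "average ranks",
    censor_policy = policy
  )
}
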