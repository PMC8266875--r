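test_that("size-weighted overall mean reproduces the all-products row", {
  s <- paper_table2_summaries()
  expect_equal(round(weighted_overall_mean(s, 5), 2), 1.28)
  expect_equal(round(weighted_overall_mean(s, 10), 2), 1.33)
  expect_equal(round(weighted_overall_mean(s, 20), 2), 1.37)

  # invariance: identical group means collapse to that mean exactly
  flat <- tibble::tibble(product_type = c("black", "green"), brew_time_min = 5,
                         n_brands = c(5L, 3L), mean_mg_per_L = 0.7,
                         sd_mg_per_L = c(0.2, 0.1))
  expect_identical(weighted_overall_mean(flat, 5), 0.7)

  # weighted mean bounded by group means
  g <- dplyr::filter(s, brew_time_min == 10)
  wm <- weighted_overall_mean(s, 10)
  expect_gte(wm, min(g$mean_mg_per_L))
  expect_lte(wm, max(g$mean_mg_per_L))

  expect_error(weighted_overall_mean(s, 7), class = "fluorisk_error_empty")
})

test_that("pooled SD matches the sum-of-squares oracle and raw-data reconstruction", {
  s <- paper_table2_summaries()

  # independent oracle: explicit within/between decomposition
  g <- table2_5min()
  gm <- sum(g$n_brands * g$mean_mg_per_L) / sum(g$n_brands)
  oracle <- sqrt((sum((g$n_brands - 1) * g$sd_mg_per_L^2) +
                    sum(g$n_brands * (g$mean_mg_per_L - gm)^2)) /
                   (sum(g$n_brands) - 1))
  expect_equal(pooled_sd(s, 5), oracle, tolerance = 1e-12)
  expect_equal(round(oracle, 3), 1.112)          # frozen oracle value
  expect_lte(abs(pooled_sd(s, 5) - 1.12), 0.02)  # published 1.12, input rounding

  # single group: that group's SD exactly
  one <- dplyr::filter(s, product_type == "black", brew_time_min == 5)
  expect_identical(pooled_sd(one, 5), 1.10)

  # equivalence on raw data: summarising then pooling equals direct SD of the
  # per-brand values (brute-force reconstruction over synthetic datasets)
  set.seed(42)
  for (rep in 1:5) {
    vals <- list(a = rnorm(4, 2, 0.5), b = rnorm(3, 1, 0.3), c = rnorm(5, 3, 1))
    summ <- purrr::imap_dfr(vals, function(v, nm) {
      tibble::tibble(product_type = "black", brew_time_min = 5, n_brands = length(v),
                     mean_mg_per_L = mean(v), sd_mg_per_L = sd(v))
    })
    expect_equal(pooled_sd(summ, 5), sd(unlist(vals)), tolerance = 1e-10)
  }

  # identical mean and SD across groups: decomposition collapses to the
  # within term. Brute-force oracle: three raw triples {m - s, m, m + s}
  # each have mean m and sample SD s; their 9-value pool has sample SD
  # sqrt(6 s^2 / 8), which the decomposition must reproduce (the pooled
  # sample SD is below s because pooling spends extra degrees of freedom
  # on group means that happen to coincide).
  m <- 1.5; s_g <- 0.25
  raw <- rep(c(m - s_g, m, m + s_g), times = 3)
  expect_equal(sd(c(m - s_g, m, m + s_g)), s_g) # each group's SD is s
  same <- tibble::tibble(product_type = c("black", "green", "white"),
                         brew_time_min = 5, n_brands = c(3L, 3L, 3L),
                         mean_mg_per_L = m, sd_mg_per_L = s_g)
  expect_equal(pooled_sd(same, 5), sd(raw), tolerance = 1e-12)

  tiny <- tibble::tibble(product_type = "white", brew_time_min = 5,
                         n_brands = 1L, mean_mg_per_L = 0.2, sd_mg_per_L = 0)
  expect_error(pooled_sd(tiny, 5), class = "fluorisk_error_insufficient_data")
})

test_that("normality gate accepts normal and rejects lognormal samples", {
  reps <- 200
  p_norm <- vapply(seq_len(reps), function(i) {
    normality_check(withr::with_seed(i, rnorm(50)))$p_value
  }, numeric(1))
  expect_gte(mean(p_norm > 0.05), 0.95)

  p_lnorm <- vapply(seq_len(reps), function(i) {
    normality_check(withr::with_seed(i, rlnorm(200, 0, 1)))$p_value
  }, numeric(1))
  expect_gte(mean(p_lnorm < 0.05), 0.95)

  expect_error(normality_check(c(1, 2)), class = "fluorisk_error_insufficient_data")
  expect_error(normality_check(rep(3, 10)), class = "fluorisk_error_degenerate")
})

test_that("Mann-Whitney comparison matches the enumeration oracle and is symmetric", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- compare_groups(a, b)
  oracle <- enumerate_mw(a, b)
  expect_equal(unname(res$statistic), oracle$U) # U = 0: every a below every b
  expect_equal(res$p_value, oracle$p)           # exact two-sided p = 0.1
  expect_equal(res$p_value, 0.1)
  expect_match(res$method, "exact")

  # oracle agreement on random tie-free small samples
  for (i in 1:10) {
    x <- withr::with_seed(i, round(rnorm(4), 6))
    y <- withr::with_seed(100 + i, round(rnorm(5, 0.5), 6))
    expect_equal(compare_groups(x, y)$p_value, enumerate_mw(x, y)$p,
                 tolerance = 1e-12)
  }

  # symmetry of the two-sided p
  expect_equal(compare_groups(a, b)$p_value, compare_groups(b, a)$p_value)

  # identical multisets: p = 1 (ties force the approximate path)
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1, tolerance = 1e-9)
  expect_match(same$method, "approximation")

  # fully degenerate all-ties input
  expect_equal(compare_groups(c(1, 1, 1), c(1, 1, 1))$p_value, 1)

  expect_error(compare_groups(numeric(0), b), class = "fluorisk_error_empty")
})

test_that("pairwise comparisons produce a tidy table over type pairs", {
  synth <- generate_infusion_study(study_design(), seed = 5)
  pw <- pairwise_comparisons(synth, brew_time_min = 5)
  expect_equal(nrow(pw), choose(5, 2))
  expect_true(all(pw$p_value >= 0 & pw$p_value <= 1))
  holm <- pairwise_comparisons(synth, brew_time_min = 5, adjust = "holm")
  expect_true(all(holm$p_adjusted >= holm$p_value - 1e-12))
})

test_that("censored Spearman reproduces the water-chemistry correlations", {
  w <- paper_water_profiles()
  infusible <- paper_infusible_by_water()$mean_mg_per_L

  # hand-rank oracle: x-ranks (2,2,2,4,5,6) after DL ties, y-ranks (3,1,2,4,5,6)
  rho_oracle <- stats::cor(c(2, 2, 2, 4, 5, 6), c(3, 1, 2, 4, 5, 6))
  res_f <- spearman_censored(w$fluoride_mg_per_L, infusible,
                             censored = w$fluoride_censored)
  expect_equal(res_f$rho, rho_oracle, tolerance = 1e-12)
  expect_equal(round(res_f$rho, 3), 0.941)
  expect_lt(res_f$p_value, 0.01)

  # pH ordering is identical to the infusible ordering: rho = 1
  res_ph <- spearman_censored(w$pH, infusible)
  expect_equal(res_ph$rho, 1)
  expect_lt(res_ph$p_value, 0.01)

  # antitone case
  x <- c(0.1, 0.4, 0.9, 1.7, 2.2)
  expect_equal(spearman_censored(x, rev(sort(x)))$rho, -1)

  # symmetry when nothing is censored
  y <- c(3, 1, 4, 1.5, 9)
  expect_equal(spearman_censored(x, y)$rho, spearman_censored(y, x)$rho)

  # policies differ only through ties/drops
  res_half <- spearman_censored(w$fluoride_mg_per_L, infusible,
                                censored = w$fluoride_censored,
                                policy = "substitute_half_dl")
  expect_equal(res_half$rho, res_f$rho) # same ranks: all censored tie below
  res_drop <- spearman_censored(w$fluoride_mg_per_L, infusible,
                                censored = w$fluoride_censored,
                                policy = "drop_censored")
  expect_equal(res_drop$n, 3)
  expect_equal(res_drop$rho, 1) # remaining three waters are concordant

  expect_error(
    spearman_censored(w$fluoride_mg_per_L[1:4], infusible[1:4],
                      censored = w$fluoride_censored[1:4],
                      policy = "drop_censored"),
    class = "fluorisk_error_insufficient_data"
  )
})
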