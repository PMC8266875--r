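test_that("deterministic CDI and HQ follow the dose equation", {
  # annihilator and hand arithmetic (EF * ED / AT = 1)
  expect_equal(cdi_point(0, 2, 365, 30, 60, 365 * 30), 0)
  expect_equal(cdi_point(2.54, 1, 365, 10, 30, 3650), 2.54 / 30, tolerance = 1e-12)
  # homogeneity of degree -1 in BW
  expect_equal(cdi_point(2.54, 1, 365, 10, 60, 3650),
               cdi_point(2.54, 1, 365, 10, 30, 3650) / 2, tolerance = 1e-12)

  expect_equal(hq_point(0.06, 0.06), 1.0)
  expect_equal(hq_point(0, 0.12), 0)
  expect_equal(round(hq_point(0.0696, 0.06), 2), 1.16)

  expect_error(cdi_point(1, 1, 1, 1, 0, 1), class = "fluorisk_error_domain")
  expect_error(cdi_point(1, 1, 1, 1, 1, -1), class = "fluorisk_error_domain")
  expect_error(hq_point(0.05, 0), class = "fluorisk_error_domain")
})

test_that("scenario construction applies defaults and validates", {
  sc <- exposure_scenario("children", "black",
                          C = dist_point(2), DI = dist_point(0.3),
                          EF = dist_point(365), ED = dist_point(6),
                          BW = dist_point(22))
  expect_equal(sc$rfd, 0.06)
  expect_equal(exposure_scenario("adults", "black", dist_point(2),
                                 dist_point(0.3), dist_point(365),
                                 dist_point(45), dist_point(60))$rfd, 0.12)

  # untruncated normal inputs are truncated at zero (physical quantities)
  sc2 <- exposure_scenario("children", "black",
                           C = dist_normal(2, 1), DI = dist_point(0.3),
                           EF = dist_point(365), ED = dist_point(6),
                           BW = dist_point(22))
  expect_equal(sc2$specs$C$truncate, c(0, Inf))
  expect_true(all(dist_sample(sc2$specs$C, 1000, seed = 1) >= 0))

  expect_error(exposure_scenario("children", "black", dist_point(2),
                                 dist_point(0.3), dist_point(365),
                                 dist_point(6), dist_point(22), rfd = -1),
               class = "fluorisk_error_domain")
  expect_error(exposure_scenario("children", "black", dist_point(2),
                                 dist_point(0.3), dist_point(365),
                                 dist_point(6), dist_point(22),
                                 at_rule = "fixed"),
               class = "fluorisk_error_domain")
})

test_that("all-point scenarios propagate to the closed form with zero variance", {
  cf <- closed_form_scenario("all_point")
  res <- run_monte_carlo(cf$scenario, 200, seed = 4)
  expect_equal(res$draws$CDI, rep(2.54 / 30, 200), tolerance = 1e-12)
  expect_equal(res$draws$HQ, rep(2.54 / 30 / 0.06, 200), tolerance = 1e-12)
  expect_equal(round(res$draws$HQ[1], 4), 1.4111)

  s <- risk_summary(res)
  expect_equal(s$cdi_p5, s$cdi_mean, tolerance = 1e-12)
  expect_equal(s$cdi_p5, s$cdi_p95, tolerance = 1e-12)
  expect_equal(s$p_hq_gt_1, 1)
})

test_that("Monte Carlo runs are bit-reproducible and substream-isolated", {
  cf <- closed_form_scenario("all_lognormal")
  r1 <- run_monte_carlo(cf$scenario, 2000, seed = 21)
  r2 <- run_monte_carlo(cf$scenario, 2000, seed = 21)
  expect_identical(r1$draws, r2$draws)

  # replacing one input's spec leaves other inputs' draws untouched
  sc_mod <- cf$scenario
  sc_mod$specs$DI <- dist_point(0.5)
  r3 <- run_monte_carlo(sc_mod, 2000, seed = 21)
  expect_identical(r1$draws$C, r3$draws$C)
  expect_identical(r1$draws$BW, r3$draws$BW)
  expect_false(identical(r1$draws$DI, r3$draws$DI))
})

test_that("lognormal concentration propagates to the analytic CDI quantile", {
  cf <- closed_form_scenario("lognormal_C")
  res <- run_monte_carlo(cf$scenario, 10000, seed = 31)
  p95_mc <- unname(quantile(res$draws$CDI, 0.95, type = 7))
  p95_true <- dist_quantile(cf$cdi_dist, 0.95)
  expect_lt(abs(p95_mc - p95_true) / p95_true, 0.02)
})

test_that("ED cancels under the ED x 365 averaging-time rule", {
  base <- list(C = dist_point(2.54), DI = dist_point(0.5),
               EF = dist_point(300), BW = dist_point(25))
  sc_a <- exposure_scenario("children", "black", base$C, base$DI, base$EF,
                            ED = dist_point(3), BW = base$BW)
  sc_b <- exposure_scenario("children", "black", base$C, base$DI, base$EF,
                            ED = dist_point(30), BW = base$BW)
  ra <- run_monte_carlo(sc_a, 50, seed = 1)
  rb <- run_monte_carlo(sc_b, 50, seed = 1)
  expect_equal(ra$draws$CDI, rb$draws$CDI, tolerance = 1e-12)

  # but not under a fixed averaging time
  sc_c <- exposure_scenario("children", "black", base$C, base$DI, base$EF,
                            ED = dist_point(3), BW = base$BW,
                            at_rule = "fixed", at_days = 365 * 70)
  rc <- run_monte_carlo(sc_c, 50, seed = 1)
  expect_false(isTRUE(all.equal(ra$draws$CDI, rc$draws$CDI)))
})

test_that("scaling the concentration scales every CDI and HQ draw linearly", {
  mk <- function(cval) {
    exposure_scenario("teenagers", "green", C = dist_point(cval),
                      DI = dist_triangular(0.2, 0.4, 0.8),
                      EF = dist_point(365), ED = dist_point(15),
                      BW = dist_triangular(35, 52, 75))
  }
  r1 <- run_monte_carlo(mk(1.0), 500, seed = 9)
  r3 <- run_monte_carlo(mk(3.0), 500, seed = 9)
  expect_equal(r3$draws$CDI, 3 * r1$draws$CDI, tolerance = 1e-12)
  expect_equal(r3$draws$HQ, 3 * r1$draws$HQ, tolerance = 1e-12)
})

test_that("summaries: exceedance semantics and quantile estimator", {
  cf <- closed_form_scenario("all_lognormal")
  res <- run_monte_carlo(cf$scenario, 5000, seed = 13)

  s <- risk_summary(res, cdi_reference = res$scenario$rfd)
  # P(HQ > 1) == P(CDI > RfD) exactly, per draw
  expect_identical(mean(res$draws$HQ > 1),
                   mean(res$draws$CDI > res$scenario$rfd))
  expect_equal(s$p_hq_gt_1, s$p_cdi_exceeds)

  # counting case
  fake <- res
  fake$draws <- tibble::tibble(CDI = c(0.03, 0.09), HQ = c(0.5, 1.5))
  fake$n_iterations <- 2L
  expect_equal(risk_summary(fake)$p_hq_gt_1, 0.5)

  # uniform draws: p95 within 0.01 of 0.95 at n = 1e4
  u <- res
  udraws <- dist_sample(dist_uniform(0, 1), 1e4, seed = 77)
  u$draws <- tibble::tibble(CDI = udraws, HQ = udraws)
  u$n_iterations <- 10000L
  expect_lt(abs(risk_summary(u)$cdi_p95 - 0.95), 0.01)

  expect_error(risk_summary(run_monte_carlo(cf$scenario, 1, seed = 2)),
               class = "fluorisk_error_insufficient_data")
})

test_that("tidy and glance expose the draws and the digest", {
  cf <- closed_form_scenario("lognormal_C")
  res <- run_monte_carlo(cf$scenario, 100, seed = 6)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 100)
  expect_true(all(c("iteration", "C", "DI", "EF", "ED", "BW", "AT", "CDI", "HQ")
                  %in% names(td)))
  expect_equal(td$HQ, td$CDI / res$scenario$rfd, tolerance = 1e-12)

  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_iterations, 100L)
  expect_equal(gl$product_type, "black")
  expect_lte(gl$cdi_p5, gl$cdi_p95)
})
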