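Package: fluorisk
Title: Probabilistic Health-Risk Assessment of Fluoride Exposure from Brewed Tea
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for probabilistic non-carcinogenic health-risk assessment of
    fluoride ingested from tea and herbal infusions. Provides validated long-format
    containers for brand-level infusion measurements (with censored below-detection-limit
    values as a first-class state), the descriptive and nonparametric statistics used in
    infusion studies (size-weighted overall means, pooled standard deviations,
    Shapiro-Wilk gating, exact and tie-corrected Mann-Whitney comparisons, Spearman rank
    correlation under censoring policies), seeded parametric distribution specifications
    with closed-form moments and quantiles, a deterministic triangular-distribution
    fitter, a reproducible Monte Carlo engine for chronic daily intake (CDI) and hazard
    quotient (HQ) propagation with percentile and exceedance summaries,
    contribution-to-variance sensitivity analysis, a study-shaped synthetic data
    generator, and an end-to-end reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
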