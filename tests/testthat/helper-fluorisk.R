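# Table-2-shaped summary fixture built in code (5-min groups)
table2_5min <- function() {
  dplyr::filter(paper_table2_summaries(), brew_time_min == 5)
}

# brute-force two-sided Mann-Whitney p by enumerating all labelings of the
# combined sample (tie-free inputs only); U counts pairs with a > b
enumerate_mw <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  idx <- utils::combn(length(pooled), n_a)
  u_of <- function(av, bv) sum(outer(av, bv, ">"))
  u_obs <- u_of(a, b)
  u_all <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  # two-sided: double the smaller tail of the symmetric null
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  list(U = u_obs, p = min(p, 1))
}
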