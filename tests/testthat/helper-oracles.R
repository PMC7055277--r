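# Shared fixtures and independent oracles used across the test files.

# trip table straight from zone-index pairs (bypasses coordinate emission)
trip_table_from_indices <- function(origin, dest) {
  trips <- data.frame(origin_zone = origin, dest_zone = dest)
  class(trips) <- c("trip_table", "data.frame")
  trips
}

# analytic stretched-exponential CDF on [k_min, Inf)
se_cdf <- function(k, beta, lambda, k_min) {
  1 - exp(-lambda * (k^beta - k_min^beta))
}

# chi-square goodness-of-fit of observed counts against expected probabilities,
# pooling cells with expected count below `min_expected`
chisq_gof_p <- function(obs, prob, min_expected = 5) {
  n <- sum(obs)
  exp_ <- n * prob / sum(prob)
  keep <- exp_ >= min_expected
  o <- c(obs[keep], sum(obs[!keep]))
  e <- c(exp_[keep], sum(exp_[!keep]))
  use <- e > 0
  stat <- sum((o[use] - e[use])^2 / e[use])
  stats::pchisq(stat, df = sum(use) - 1, lower.tail = FALSE)
}

# small reference layout reused by several kernel/spectral tests
ref_layout_800 <- function() make_zone_layout("uniform-random", 800, c(14, 14),
                                              seed = 101)
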