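# Shared fixtures: all synthetic, built in code at test time.

null_config <- function(n, seed, ...) {
  cohort_config(n, beta_sbp_per5 = rep(0, 9), beta_dbp_per5 = rep(0, 9),
                seed = seed, ...)
}

# data with exact sample moments (for summary-vs-raw t-test oracles)
exact_moments <- function(n, mean, sd, seed) {
  set.seed(seed)
  z <- rnorm(n)
  mean + sd * (z - mean(z)) / stats::sd(z)
}

expect_one_row <- function(res) {
  expect_s3_class(res, "data.frame")
  expect_equal(nrow(res), 1L)
}
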