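test_that("average methylation pools unmasked sites", {
  panel <- nppa_panel()
  vals <- matrix(50, 3, 9)
  mm <- methylation_matrix(vals, panel, paste0("s", 1:3))
  expect_equal(unname(average_methylation(mm)), rep(50, 3))
  vals2 <- matrix(NA_real_, 2, 9)
  vals2[1, 1:2] <- c(30, 70)
  mm2 <- methylation_matrix(vals2, panel, c("s1", "s2"))
  expect_message(avg <- average_methylation(mm2), "masked")
  expect_equal(unname(avg), c(50, NA))
})

test_that("cohorts at published means reproduce the published average", {
  cfg <- null_config(20000, seed = 55)
  ch <- generate_cohort(cfg)
  expect_lt(abs(mean(average_methylation(ch$methylation)) - 50.55), 0.2)
})

test_that("truncated product statistics follow the definitions", {
  expect_equal(tpm_statistic(c(0.02, 0.5, 0.04), 0.1), 8e-4)
  expect_equal(tpm_statistic(c(0.5, 0.9), 0.1), 1)
  expect_equal(tpm_statistic(c(0.2, 0.5), 1), 0.1)
  w1 <- wtpm_statistic(c(0.01, 0.04), c(-1, -1), 0.1)
  expect_equal(unname(w1$weights), c(0.5, 0.5))
  expect_equal(w1$W, 0.02)
  w2 <- wtpm_statistic(c(0.03, 0.5), c(2, 0.1), 0.1)
  expect_equal(w2$W, 0.03)
  expect_equal(w2$n_included, 1L)
  # hand-computed: 0.01^0.75 * 0.04^0.25
  w3 <- wtpm_statistic(c(0.01, 0.04), c(-3, -1), 0.1)
  expect_equal(w3$W, 0.01^0.75 * 0.04^0.25, tolerance = 1e-12)
  expect_equal(w3$W, 0.0141421356, tolerance = 1e-6)
  expect_warning(w0 <- wtpm_statistic(c(0.01, 0.04), c(0, 0), 0.1),
                 "equal weights")
  expect_equal(w0$W, 0.02)
  expect_error(tpm_statistic(c(0.5, 1.4)), "\\[0, 1\\]")
  expect_error(wtpm_statistic(0.5, c(1, 2)), "lengths differ")
})

test_that("W is invariant to CpG ordering", {
  set.seed(61)
  for (rep in 1:10) {
    p <- runif(9)
    b <- rnorm(9)
    o <- sample(9)
    expect_equal(wtpm_statistic(p, b)$W, wtpm_statistic(p[o], b[o])$W,
                 tolerance = 1e-12)
  }
})

test_that("wTPM and TPM rank identically at a fixed inclusion count", {
  set.seed(62)
  k <- 3
  Ws <- replicate(50, {
    p <- c(runif(k, 0, 0.1), runif(6, 0.2, 1))  # exactly k included
    c(tpm_statistic(p, 0.1), wtpm_statistic(p, rep(1, 9), 0.1)$W)
  })
  expect_equal(order(Ws[1, ]), order(Ws[2, ]))
})

test_that("closed-form independent p-value matches simple cases", {
  expect_equal(tpm_pvalue_independent(0.05, 1, 1), 0.05)
  expect_equal(tpm_pvalue_independent(1, 9, 0.1), 1)
  expect_error(tpm_pvalue_independent(0.5, 0), "positive")
  expect_error(tpm_pvalue_independent(0, 3), "\\(0, 1\\]")
  # L = 1, tau = 0.1: P(W <= w) = w for w <= tau, tau otherwise
  expect_equal(tpm_pvalue_independent(0.05, 1, 0.1), 0.05)
  expect_equal(tpm_pvalue_independent(0.5, 1, 0.1), 0.1)
})

test_that("closed form matches a Monte Carlo null (module-scale draws)", {
  set.seed(63)
  ndraw <- 2e5
  u <- matrix(runif(ndraw * 9), ndraw, 9)
  logw <- rowSums(ifelse(u <= 0.1, log(u), 0))
  for (W in c(1e-6, 1e-4, 0.01)) {
    mc <- mean(logw <= log(W) + 1e-15 & logw < 0)
    exact <- tpm_pvalue_independent(W, 9, 0.1)
    se <- sqrt(exact * (1 - exact) / ndraw)
    expect_lt(abs(mc - exact), 3 * se + 1e-12)
  }
})

test_that("permutation machinery reproduces per-CpG Wald fits (FWL)", {
  ch <- generate_cohort(null_config(400, seed = 64))
  w <- wtpm_permutation_pvalue(ch$methylation, ch$phenotypes, "sbp",
                               B = 100, seed = 1)
  a <- associate_all(ch$methylation, ch$phenotypes, outcomes = "sbp")
  expect_equal(unname(w$beta_single), a$beta_per5, tolerance = 1e-10)
  expect_equal(unname(w$p_single), a$p, tolerance = 1e-10)
  expect_error(wtpm_permutation_pvalue(ch$methylation, ch$phenotypes,
                                       "sbp", B = 50, seed = 1),
               "at least 100")
})

test_that("permutation p agrees with the closed form for independent CpGs", {
  cfg <- null_config(1000, cpg_corr = diag(9), seed = 65)
  ch <- generate_cohort(cfg)
  w <- wtpm_permutation_pvalue(ch$methylation, ch$phenotypes, "sbp",
                               B = 9999, seed = 66, statistic = "tpm")
  exact <- tpm_pvalue_independent(w$W, 9, 0.1)
  se <- sqrt(exact * (1 - exact) / w$B)
  expect_lt(abs(w$p_combined - exact), 3 * se + 1 / (w$B + 1))
})

test_that("permutation p is (discretely) uniform under the null", {
  B <- 199
  ps <- vapply(1:120, function(i) {
    ch <- generate_cohort(null_config(300, seed = 70000 + i))
    wtpm_permutation_pvalue(ch$methylation, ch$phenotypes, "sbp",
                            B = B, seed = 70000 + i)$p_combined
  }, numeric(1))
  expect_true(all(abs(ps * (B + 1) - round(ps * (B + 1))) < 1e-9))
  # valid p: P(p <= a) ~ a (the statistic has an atom at W = 1 when no
  # CpG passes truncation, so the distribution is super-uniform near 1
  # but must stay calibrated below)
  for (a in c(0.25, 0.5)) {
    se3 <- 3 * sqrt(a * (1 - a) / length(ps))
    expect_lt(abs(mean(ps <= a) - a), se3 + 0.01)
  }
})

test_that("wTPM detects a shared signal (power at study scale)", {
  hits <- vapply(1:10, function(i) {
    cfg <- cohort_config(2500, beta_sbp_per5 = c(rep(-1, 5), rep(0, 4)),
                         beta_dbp_per5 = rep(0, 9), seed = 80000 + i)
    ch <- generate_cohort(cfg)
    wtpm_permutation_pvalue(ch$methylation, ch$phenotypes, "sbp",
                            B = 999, seed = 80000 + i)$p_combined < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("binary-outcome route runs and respects determinism", {
  ch <- generate_cohort(null_config(600, seed = 67))
  w1 <- wtpm_permutation_pvalue(ch$methylation, ch$phenotypes,
                                "hypertension", B = 199, seed = 2)
  w2 <- wtpm_permutation_pvalue(ch$methylation, ch$phenotypes,
                                "hypertension", B = 199, seed = 2)
  expect_identical(w1$p_combined, w2$p_combined)
  expect_true(w1$p_combined > 0 && w1$p_combined <= 1)
})

test_that("gene_based_tests assembles both routes per outcome", {
  ch <- generate_cohort(null_config(400, seed = 68))
  g <- gene_based_tests(ch$methylation, ch$phenotypes,
                        outcomes = c("sbp", "hypertension"),
                        B = 199, seed = 3)
  expect_equal(nrow(g), 4L)
  expect_setequal(g$method, c("average", "wTPM"))
  expect_true(all(g$p > 0 & g$p <= 1))
})
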