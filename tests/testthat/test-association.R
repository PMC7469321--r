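test_that("hypertension classification follows the clinical rule", {
  expect_true(classify_hypertension(140, 80, FALSE))
  expect_false(classify_hypertension(139, 89, FALSE))
  expect_true(classify_hypertension(120, 70, TRUE))
  expect_true(classify_hypertension(120, 90, FALSE))
  expect_equal(classify_hypertension(c(150, 120), c(80, 80), c(FALSE, FALSE)),
               c(TRUE, FALSE))
  expect_error(classify_hypertension(-1, 80, FALSE), "positive")
})

test_that("phenotype helpers compute means and BMI", {
  expect_equal(mean_bp(c(120, 122, 124)), 122)
  expect_equal(mean_bp(c(100, 110, 120)), 110)
  expect_equal(mean_bp(rbind(c(90, 90, 90), c(100, 110, 120))), c(90, 110))
  expect_error(mean_bp(c(120, 130)), "three readings")
  expect_equal(compute_bmi(81, 180), 25)
  expect_equal(compute_bmi(50, 200), 12.5)
  expect_error(compute_bmi(0, 170), "positive")
})

test_that("summary t test matches a raw-data t test with exact moments", {
  cases <- list(c(80, 10.2, 2.1, 95, 9.6, 2.4),
                c(200, 50, 5, 150, 49, 5.5),
                c(30, 0.1, 0.02, 40, 0.11, 0.025))
  for (cs in cases) {
    x1 <- exact_moments(cs[1], cs[2], cs[3], seed = 31)
    x2 <- exact_moments(cs[4], cs[5], cs[6], seed = 32)
    ours <- two_sample_t_summary(cs[1], cs[2], cs[3], cs[4], cs[5], cs[6])
    ref <- t.test(x1, x2, var.equal = TRUE)
    expect_lt(abs(ours$p - ref$p.value), 1e-10)
    expect_equal(ours$df, unname(ref$parameter))
  }
  eq <- two_sample_t_summary(50, 5, 1, 60, 5, 2)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  expect_error(two_sample_t_summary(1, 5, 1, 60, 5, 2), "at least 2")
  expect_error(two_sample_t_summary(50, 5, 0, 60, 5, 2), "positive")
})

test_that("chi-square 2x2 matches the uncorrected Pearson reference", {
  tabs <- list(c(281, 1108, 301, 808), c(12, 34, 56, 78), c(5, 5, 5, 5))
  for (tb in tabs) {
    ours <- chi_square_2x2(tb[1], tb[2], tb[3], tb[4])
    ref <- suppressWarnings(
      chisq.test(matrix(tb, 2, byrow = TRUE), correct = FALSE))
    expect_lt(abs(ours$statistic - unname(ref$statistic)), 1e-10)
    expect_lt(abs(ours$p - ref$p.value), 1e-12)
  }
  prop <- chi_square_2x2(10, 20, 30, 60)
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p, 1)
  expect_error(chi_square_2x2(0, 0, 3, 4), "margin")
})

test_that("linear fit equals lm and the simple-regression closed form", {
  ch <- generate_cohort(null_config(500, seed = 21))
  covs <- ch$phenotypes[, covariate_sets()$bp]
  m <- ch$methylation$values[, 4]
  f <- fit_linear_bp(ch$phenotypes$sbp, m, covs, site = "CpG4")
  ref <- lm(ch$phenotypes$sbp ~ I(m / 5) + ., data = covs)
  expect_equal(f$beta_per5, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(f$se, unname(sqrt(diag(vcov(ref)))[2]), tolerance = 1e-10)
  expect_equal(f$n_used, 500L)
  # intercept + one predictor with orthogonal noise: closed-form slope
  set.seed(22)
  x <- rnorm(100, 50, 5)
  e <- resid(lm(rnorm(100) ~ x))          # exactly orthogonal to x
  y <- 2 * (x / 5) + e
  f2 <- fit_linear_bp(y, x, data.frame(row.names = seq_along(x)))
  slope <- cov(y, x / 5) / var(x / 5)
  expect_lt(abs(f2$beta_per5 - slope), 1e-10)
  expect_lt(abs(f2$beta_per5 - 2), 1e-10)
})

test_that("degenerate designs are rejected with informative errors", {
  ch <- generate_cohort(null_config(100, seed = 23))
  covs <- ch$phenotypes[, covariate_sets()$bp]
  expect_error(fit_linear_bp(ch$phenotypes$sbp, rep(50, 100), covs),
               "collinear.*meth_per5")
  expect_error(
    fit_logistic_htn(rep(1L, 100), ch$methylation$values[, 1], covs),
    "single class")
  expect_error(
    fit_linear_bp(ch$phenotypes$sbp[1:20], ch$methylation$values[1:20, 1],
                  covs[1:20, ]),
    "30 complete cases")
  # perfect separation: outcome is a deterministic threshold of methylation
  m <- seq(10, 90, length.out = 60)
  y <- as.integer(m > 50)
  expect_error(fit_logistic_htn(y, m, data.frame(age = rnorm(60))),
               "separation")
})

test_that("logistic fit matches glm and is scale-equivariant", {
  ch <- generate_cohort(null_config(800, seed = 24))
  covs <- ch$phenotypes[, covariate_sets()$htn]
  m <- ch$methylation$values[, 1]
  f <- fit_logistic_htn(ch$phenotypes$hypertension, m, covs)
  ref <- glm(ch$phenotypes$hypertension ~ I(m / 5) + ., data = covs,
             family = binomial())
  expect_equal(f$beta_per5, unname(coef(ref)[2]), tolerance = 1e-7)
  expect_equal(f$or_value, exp(f$beta_per5))
  expect_true(f$ci_low < f$or_value && f$or_value < f$ci_high)
  # multiplying methylation by 10 rescales beta by 1/10; OR per 5 units of
  # the new scale changes, but mapping back reproduces the original
  f10 <- fit_logistic_htn(ch$phenotypes$hypertension, m * 10, covs)
  expect_equal(f10$beta_per5 * 10, f$beta_per5, tolerance = 1e-6)
})

test_that("fits are invariant to covariate order and affine rescaling", {
  ch <- generate_cohort(null_config(600, seed = 25))
  covs <- ch$phenotypes[, covariate_sets()$bp]
  m <- ch$methylation$values[, 2]
  f1 <- fit_linear_bp(ch$phenotypes$sbp, m, covs)
  f2 <- fit_linear_bp(ch$phenotypes$sbp, m, rev(covs))
  covs3 <- covs; covs3$age <- (covs3$age - 50) / 10; covs3$bmi <- covs3$bmi * 3
  f3 <- fit_linear_bp(ch$phenotypes$sbp, m, covs3)
  expect_equal(f1$beta_per5, f2$beta_per5, tolerance = 1e-10)
  expect_equal(f1$p, f2$p, tolerance = 1e-10)
  expect_equal(f1$beta_per5, f3$beta_per5, tolerance = 1e-8)
  expect_equal(f1$p, f3$p, tolerance = 1e-8)
})

test_that("type-I error of the linear fit is nominal", {
  # 1000 independent null fits at n = 500; rejection at 0.05 should land
  # in [0.035, 0.065]
  pvals <- vapply(1:1000, function(i) {
    ch <- generate_cohort(null_config(500, seed = 40000 + i))
    covs <- ch$phenotypes[, covariate_sets()$bp]
    fit_linear_bp(ch$phenotypes$sbp,
                  ch$methylation$values[, (i %% 9) + 1], covs)$p
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})
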