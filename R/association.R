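## Single-CpG association of methylation with blood pressure (linear) and
## prevalent hypertension (logistic), per 5% methylation, under the study's
## two covariate sets; plus the descriptive group comparisons (pooled t
## test from summary moments, Pearson chi-square) and phenotype helpers.

#' The two adjustment sets used by the association models
#'
#' Blood-pressure (linear) models additionally adjust for antihypertensive
#' medication; the hypertension (logistic) model must not, since treatment
#' is part of the case definition.
#'
#' @return Named list of covariate column names: `bp` and `htn`.
#' @export
covariate_sets <- function() {
  base <- c("age", "sex", "education", "current_smoking",
            "current_drinking", "bmi", "fasting_glucose", "ldl_c", "hdl_c")
  list(bp = c(base, "antihypertensive_treatment"), htn = base)
}

#' Classify prevalent hypertension
#'
#' SBP >= 140 mmHg and/or DBP >= 90 mmHg, or current antihypertensive
#' treatment.
#'
#' @param sbp,dbp Blood pressure in mmHg (vectorized).
#' @param treated Treatment flag (logical or 0/1).
#' @return Logical vector.
#' @export
classify_hypertension <- function(sbp, dbp, treated) {
  if (any(sbp <= 0 | dbp <= 0, na.rm = TRUE))
    stop2("blood pressures must be positive")
  sbp >= 140 | dbp >= 90 | as.logical(treated)
}

#' Mean of three blood-pressure readings
#'
#' @param readings Numeric vector of exactly three readings, or an n x 3
#'   matrix (one row per participant).
#' @return Arithmetic mean (per row for a matrix).
#' @export
mean_bp <- function(readings) {
  if (is.matrix(readings)) {
    if (ncol(readings) != 3L)
      stop2("expected exactly three readings per participant, got %d",
            ncol(readings))
    return(rowMeans(readings))
  }
  if (length(readings) != 3L)
    stop2("expected exactly three readings, got %d", length(readings))
  mean(readings)
}

#' Body mass index
#'
#' @param weight_kg Weight in kilograms.
#' @param height_cm Height in centimetres.
#' @return BMI in kg/m^2.
#' @export
compute_bmi <- function(weight_kg, height_cm) {
  if (any(weight_kg <= 0) || any(height_cm <= 0))
    stop2("weight and height must be positive")
  weight_kg / (height_cm / 100)^2
}

## shared design checks: complete cases, rank, condition number
## (the outcome travels in `covariates` as `.y` but is excluded from the
## design matrix that the rank/conditioning checks run on)
build_design <- function(meth_percent, covariates) {
  covariates <- as.data.frame(covariates)
  df <- cbind(meth_per5 = meth_percent / 5, covariates)
  cc <- complete.cases(df)
  df <- df[cc, , drop = FALSE]
  X <- model.matrix(~ ., data = df[, setdiff(names(df), ".y"),
                                   drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop2("collinear design: column(s) %s are linearly dependent",
          paste(bad, collapse = ", "))
  }
  Xs <- sweep(X, 2L, sqrt(colSums(X^2)), "/")
  kap <- kappa(Xs, exact = TRUE)
  if (kap > 1e10)
    stop2("ill-conditioned design (condition number %.3g); check columns %s",
          kap, paste(colnames(X)[-1], collapse = ", "))
  list(df = df, complete = cc)
}

assoc_result <- function(site, outcome, beta, se, p, n_used, logistic = FALSE) {
  out <- data.frame(
    site = site, outcome = outcome, beta_per5 = beta, se = se,
    or_value = if (logistic) exp(beta) else NA_real_,
    ci_low = if (logistic) exp(beta - 1.96 * se) else beta - 1.96 * se,
    ci_high = if (logistic) exp(beta + 1.96 * se) else beta + 1.96 * se,
    p = p, n_used = n_used, stringsAsFactors = FALSE
  )
  class(out) <- c("AssocResult", "data.frame")
  out
}

#' Linear association of one CpG with blood pressure
#'
#' Ordinary least squares of the outcome on methylation/5 plus the
#' covariates, complete cases only; the reported effect is the mmHg change
#' per 5-percentage-point increase in methylation with its Wald t-test
#' p-value.
#'
#' @param outcome Numeric outcome (SBP or DBP, mmHg).
#' @param meth_percent One CpG's methylation (percent scale).
#' @param covariates data.frame of adjustment covariates.
#' @param site,outcome_name Labels carried into the result.
#' @return A one-row `AssocResult` data.frame.
#' @export
fit_linear_bp <- function(outcome, meth_percent, covariates,
                          site = "CpG", outcome_name = "sbp") {
  d <- build_design(meth_percent, cbind(.y = outcome, covariates))
  df <- d$df
  if (nrow(df) < 30) stop2("fewer than 30 complete cases (%d)", nrow(df))
  fit <- lm(.y ~ ., data = df)
  sm <- summary(fit)$coefficients["meth_per5", ]
  assoc_result(site, outcome_name, sm[1], sm[2], sm[4], nrow(df))
}

#' Logistic association of one CpG with prevalent hypertension
#'
#' Maximum-likelihood logistic regression (IRLS, convergence 1e-8, up to
#' 100 iterations) of the case flag on methylation/5 plus covariates.
#' Reports the odds ratio per 5% methylation with Wald 95% CI and normal
#' p-value. Errors on single-class outcomes and on detected separation.
#'
#' @param htn Case flag (0/1 or logical).
#' @param meth_percent One CpG's methylation (percent).
#' @param covariates data.frame of adjustment covariates (must not include
#'   antihypertensive treatment; see [covariate_sets()]).
#' @param site Label carried into the result.
#' @return A one-row `AssocResult` data.frame.
#' @export
fit_logistic_htn <- function(htn, meth_percent, covariates, site = "CpG") {
  y <- check_flag01(htn, "hypertension flag")
  d <- build_design(meth_percent, cbind(.y = y, covariates))
  df <- d$df
  if (nrow(df) < 30) stop2("fewer than 30 complete cases (%d)", nrow(df))
  if (length(unique(df$.y)) < 2L)
    stop2("outcome has a single class; logistic model is undefined")
  fit <- suppressWarnings(
    glm(.y ~ ., family = binomial(), data = df,
        control = list(epsilon = 1e-8, maxit = 100))
  )
  b <- coef(fit)["meth_per5"]
  if (!fit$converged || abs(b) > 15 ||
      (any(fit$fitted.values > 1 - 1e-10) && any(fit$fitted.values < 1e-10)))
    stop2("perfect separation suspected: coefficient for meth_per5 diverges")
  se <- sqrt(vcov(fit)["meth_per5", "meth_per5"])
  p <- 2 * pnorm(-abs(b / se))
  assoc_result(site, "hypertension", unname(b), se, p, nrow(df),
               logistic = TRUE)
}

#' Pooled-variance two-sample t test from summary statistics
#'
#' Student's t with pooled variance, as used to compare published group
#' means: `sp^2 = ((n1-1) sd1^2 + (n2-1) sd2^2) / (n1+n2-2)`.
#'
#' @param n1,n2 Group sizes (>= 2).
#' @param mean1,mean2 Group means.
#' @param sd1,sd2 Group standard deviations (> 0).
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
two_sample_t_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  if (n1 < 2 || n2 < 2) stop2("group sizes must be at least 2")
  if (sd1 <= 0 || sd2 <= 0) stop2("standard deviations must be positive")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  t <- (mean1 - mean2) / (sp * sqrt(1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Pearson chi-square test on a 2x2 table
#'
#' No continuity correction, 1 degree of freedom.
#'
#' @param a,b,c,d Cell counts, row-wise: `rbind(c(a, b), c(c, d))`.
#' @return List with `statistic`, `df`, `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  if (any(x < 0)) stop2("counts must be non-negative")
  n <- sum(x)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (any(c(r1, r2, c1, c2) == 0)) stop2("zero margin in 2x2 table")
  stat <- n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
  list(statistic = stat, df = 1L, p = pchisq(stat, 1L, lower.tail = FALSE))
}

#' Single-CpG association tables for all sites and outcomes
#'
#' Runs [fit_linear_bp()] for SBP and DBP (BP covariate set) and
#' [fit_logistic_htn()] (hypertension covariate set) for every CpG column,
#' then adds Benjamini-Hochberg q-values within each outcome family.
#'
#' @param mm A `MethylationMatrix`.
#' @param phenotypes Phenotype data.frame (columns per
#'   [covariate_sets()] plus `sbp`, `dbp`, `hypertension`).
#' @param outcomes Subset of `c("sbp", "dbp", "hypertension")`.
#' @return An `AssocResult` data.frame, one row per site x outcome, with
#'   a `q` column.
#' @export
associate_all <- function(mm, phenotypes,
                          outcomes = c("sbp", "dbp", "hypertension")) {
  sets <- covariate_sets()
  rows <- list()
  for (oc in outcomes) {
    covs <- phenotypes[, intersect(sets[[if (oc == "hypertension") "htn"
                                         else "bp"]], names(phenotypes)),
                       drop = FALSE]
    res <- lapply(colnames(mm$values), function(lab) {
      m <- mm$values[, lab]
      if (oc == "hypertension")
        fit_logistic_htn(phenotypes$hypertension, m, covs, site = lab)
      else
        fit_linear_bp(phenotypes[[oc]], m, covs, site = lab,
                      outcome_name = oc)
    })
    res <- do.call(rbind, res)
    res$q <- bh_qvalues(res$p)
    rows[[oc]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("AssocResult", "data.frame")
  out
}
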