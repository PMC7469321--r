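## Synthetic cohorts with correlated CpG methylation, covariates, blood
## pressure and prevalent hypertension, plus an optional read-count layer,
## so that every downstream stage can be exercised without study data.

## Table-scale defaults: per-CpG means/SDs follow the normotensive column of
## the discovery sample; covariate moments follow the pooled discovery
## sample; BP effects per 5% methylation follow the single-CpG association
## table of the discovery sample.
default_cpg_means <- function()
  c(29.02, 93.27, 22.99, 68.59, 81.96, 40.43, 50.67, 31.13, 36.84)
default_cpg_sds <- function()
  c(5.13, 2.46, 3.84, 6.36, 4.81, 6.05, 6.34, 6.33, 7.63)
default_beta_sbp <- function()
  c(-0.96, 0.31, -0.29, 0.01, 0.06, -0.48, -0.22, -0.55, -0.21)
default_beta_dbp <- function()
  c(-0.42, 0.05, -0.24, -0.11, -0.08, -0.24, -0.18, -0.30, -0.16)

default_covariate_params <- function() list(
  age = list(mean = 52.7, sd = 9.5),
  sex = list(prevalence = 0.385),          # men
  education = list(prevalence = 0.203),    # high school or above
  current_smoking = list(prevalence = 0.233),
  current_drinking = list(prevalence = 0.186),
  bmi = list(mean = 24.78, sd = 3.60),
  fasting_glucose = list(mean = 5.39, sd = 1.35),
  ldl_c = list(mean = 3.00, sd = 0.76),
  hdl_c = list(mean = 1.51, sd = 0.45)
)

## mmHg per unit covariate on SBP; DBP uses 0.55x (typical SBP:DBP effect
## ratio in population studies)
default_covariate_bp_effects <- function() c(
  age = 0.45, sex = 3, education = -1, current_smoking = 1,
  current_drinking = 2, bmi = 1.0, fasting_glucose = 1.5,
  ldl_c = 0.5, hdl_c = -2
)

## log-odds of prevalent hypertension per unit covariate (logistic mode)
default_covariate_htn_logor <- function() c(
  age = 0.06, sex = 0.3, education = -0.1, current_smoking = 0.3,
  current_drinking = 0.3, bmi = 0.12, fasting_glucose = 0.25,
  ldl_c = 0.2, hdl_c = -0.4
)

#' Exponential-decay CpG correlation matrix
#'
#' `rho^|i-j|`: nearby CpGs are highly co-methylated, distant ones less so.
#'
#' @param n_cpgs Number of sites.
#' @param rho Neighbour correlation in \[0, 1).
#' @return Correlation matrix.
#' @export
ar1_corr <- function(n_cpgs, rho = 0.7) {
  rho^abs(outer(seq_len(n_cpgs), seq_len(n_cpgs), "-"))
}

#' Configuration of a synthetic cohort
#'
#' Defaults emulate the discovery sample of a two-sample targeted
#' bisulfite study of the NPPA promoter and hypertension: 9 co-methylated
#' CpGs with population-scale means/SDs, covariate moments of a
#' middle-aged Chinese community cohort, and BP effects of roughly
#' -1 mmHg per 5% methylation at the strongest site.
#'
#' Hypertension is generated in one of two modes. In `"threshold"` mode
#' (the default when all `logor_htn_per5` are zero) the flag is *derived*:
#' SBP/DBP are simulated and the clinical rule (SBP >= 140, DBP >= 90, or
#' treated) is applied. In `"logistic"` mode (auto-selected when any
#' `logor_htn_per5` is non-zero) the flag is *drawn* from a logistic model
#' with the given per-5% log-odds, and BP/treatment are then minimally
#' edited so the clinical rule reproduces the drawn flag exactly.
#'
#' @param n_samples Number of individuals.
#' @param cpg_means,cpg_sds Per-CpG methylation mean and SD (percent).
#' @param cpg_corr Latent correlation matrix (unit diagonal, PSD).
#' @param beta_sbp_per5,beta_dbp_per5 mmHg per 5% methylation.
#' @param logor_htn_per5 Log-odds of hypertension per 5% methylation.
#' @param covariate_params Means/SDs/prevalences of the covariates.
#' @param covariate_bp_effects Named vector, mmHg per covariate unit (SBP;
#'   DBP uses `dbp_effect_scale` times this).
#' @param covariate_htn_logor Named vector, log-odds per covariate unit
#'   (logistic mode only).
#' @param mean_sbp,mean_dbp Population mean BP (mmHg) at covariate means.
#' @param noise_sd_sbp,noise_sd_dbp Residual SD (mmHg).
#' @param prev_htn Target prevalence (logistic mode intercept).
#' @param treatment_prob_given_htn P(antihypertensive treatment | case).
#' @param dbp_effect_scale DBP:SBP covariate-effect ratio.
#' @param htn_model `"auto"`, `"threshold"` or `"logistic"`.
#' @param seed Integer seed; required for reproducibility.
#' @return A validated `CohortConfig` list.
#' @export
cohort_config <- function(n_samples,
                          cpg_means = default_cpg_means(),
                          cpg_sds = default_cpg_sds(),
                          cpg_corr = ar1_corr(length(cpg_means), 0.7),
                          beta_sbp_per5 = default_beta_sbp(),
                          beta_dbp_per5 = default_beta_dbp(),
                          logor_htn_per5 = rep(0, length(cpg_means)),
                          covariate_params = default_covariate_params(),
                          covariate_bp_effects = default_covariate_bp_effects(),
                          covariate_htn_logor = default_covariate_htn_logor(),
                          mean_sbp = 130, mean_dbp = 82,
                          noise_sd_sbp = 15, noise_sd_dbp = 10,
                          prev_htn = 0.444,
                          treatment_prob_given_htn = 0.5,
                          dbp_effect_scale = 0.55,
                          htn_model = c("auto", "threshold", "logistic"),
                          seed) {
  if (missing(seed)) stop2("cohort_config requires an explicit seed")
  htn_model <- match.arg(htn_model)
  if (length(n_samples) != 1L || n_samples <= 0 || n_samples != round(n_samples))
    stop2("n_samples must be a positive integer, got %s", deparse(n_samples))
  k <- length(cpg_means)
  if (any(cpg_means < 0 | cpg_means > 100))
    stop2("cpg_means must lie in [0, 100]")
  if (length(cpg_sds) != k || any(cpg_sds <= 0))
    stop2("cpg_sds must be positive and match cpg_means in length")
  cpg_corr <- as.matrix(cpg_corr)
  if (!isTRUE(all.equal(diag(cpg_corr), rep(1, k), tolerance = 1e-8)) ||
      !isTRUE(all.equal(cpg_corr, t(cpg_corr), tolerance = 1e-8)))
    stop2("cpg_corr must be symmetric with unit diagonal")
  ev <- eigen(cpg_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop2("cpg_corr is not positive semi-definite (smallest eigenvalue %.3g)",
          min(ev))
  for (v in list(beta_sbp_per5, beta_dbp_per5, logor_htn_per5))
    if (length(v) != k)
      stop2("effect vectors must have length %d (one per CpG)", k)
  if (treatment_prob_given_htn < 0 || treatment_prob_given_htn > 1)
    stop2("treatment_prob_given_htn must lie in [0, 1]")
  if (htn_model == "auto")
    htn_model <- if (any(logor_htn_per5 != 0)) "logistic" else "threshold"

  structure(list(
    n_samples = as.integer(n_samples), cpg_means = cpg_means,
    cpg_sds = cpg_sds, cpg_corr = cpg_corr,
    beta_sbp_per5 = beta_sbp_per5, beta_dbp_per5 = beta_dbp_per5,
    logor_htn_per5 = logor_htn_per5,
    covariate_params = covariate_params,
    covariate_bp_effects = covariate_bp_effects,
    covariate_htn_logor = covariate_htn_logor,
    mean_sbp = mean_sbp, mean_dbp = mean_dbp,
    noise_sd_sbp = noise_sd_sbp, noise_sd_dbp = noise_sd_dbp,
    prev_htn = prev_htn,
    treatment_prob_given_htn = treatment_prob_given_htn,
    dbp_effect_scale = dbp_effect_scale,
    htn_model = htn_model, seed = as.integer(seed)
  ), class = "CohortConfig")
}

## covariate means implied by covariate_params (binary -> prevalence)
covariate_means <- function(cp) {
  vapply(cp, function(x) x$mean %||% x$prevalence, numeric(1))
}

draw_covariates <- function(cp, n) {
  out <- lapply(names(cp), function(nm) {
    p <- cp[[nm]]
    if (!is.null(p$prevalence)) rbinom(n, 1L, p$prevalence)
    else rnorm(n, p$mean, p$sd)
  })
  names(out) <- names(cp)
  as.data.frame(out)
}

#' Generate a synthetic cohort
#'
#' Methylation is drawn from a latent Gaussian copula: a multivariate
#' normal with the configured correlation, scaled per CpG to the target
#' mean and SD, then clipped to \[0, 100\] (clipping rather than
#' resampling keeps the draw seed-stable; at the default means/SDs it is
#' negligible). SBP/DBP are linear in centered covariates and centered
#' methylation per 5%, plus Gaussian noise. Hypertension follows the
#' configured mode (see [cohort_config()]); the classification rule
#' (SBP >= 140 and/or DBP >= 90 or treated) holds for the emitted flag in
#' both modes.
#'
#' @param config A [cohort_config()].
#' @return A `Cohort`: list with `phenotypes` (data.frame), `methylation`
#'   (`MethylationMatrix`) and `truth` (the config).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  set.seed(config$seed)
  n <- config$n_samples
  k <- length(config$cpg_means)

  ## latent Gaussian copula, moment-matched marginals, clipped
  z <- matrix(rnorm(n * k), n, k) %*% chol_psd(config$cpg_corr)
  meth <- sweep(sweep(z, 2L, config$cpg_sds, "*"), 2L, config$cpg_means, "+")
  meth <- pmin(pmax(meth, 0), 100)

  covs <- draw_covariates(config$covariate_params, n)
  cmeans <- covariate_means(config$covariate_params)
  eff <- config$covariate_bp_effects[names(covs)]
  cov_c <- sweep(as.matrix(covs), 2L, cmeans[names(covs)], "-")
  meth_c5 <- sweep(meth, 2L, config$cpg_means, "-") / 5

  sbp <- config$mean_sbp + drop(cov_c %*% eff) +
    drop(meth_c5 %*% config$beta_sbp_per5) + rnorm(n, 0, config$noise_sd_sbp)
  dbp <- config$mean_dbp + drop(cov_c %*% (eff * config$dbp_effect_scale)) +
    drop(meth_c5 %*% config$beta_dbp_per5) + rnorm(n, 0, config$noise_sd_dbp)
  dbp <- pmin(dbp, sbp - 1)   # physiological ordering

  if (config$htn_model == "threshold") {
    bp_high <- sbp >= 140 | dbp >= 90
    treated <- as.integer(bp_high & runif(n) < config$treatment_prob_given_htn)
    htn <- as.integer(bp_high | treated == 1L)
  } else {
    lo <- qlogis(config$prev_htn) +
      drop(meth_c5 %*% config$logor_htn_per5) +
      drop(cov_c %*% config$covariate_htn_logor[names(covs)])
    htn <- as.integer(runif(n) < plogis(lo))
    treated <- as.integer(htn == 1L & runif(n) < config$treatment_prob_given_htn)
    ## reconcile BP with the drawn flag so the clinical rule reproduces it:
    ## cases below both thresholds are controlled on medication; controls
    ## above a threshold are clamped just below it.
    below <- sbp < 140 & dbp < 90
    treated[htn == 1L & below] <- 1L
    clamp <- htn == 0L
    sbp[clamp] <- pmin(sbp[clamp], 139.5)
    dbp[clamp] <- pmin(dbp[clamp], 89.5)
    dbp <- pmin(dbp, sbp - 1)
  }

  sample_ids <- sprintf("S%05d", seq_len(n))
  phen <- data.frame(
    sample_id = sample_ids, sbp = sbp, dbp = dbp,
    antihypertensive_treatment = treated, hypertension = htn,
    covs, stringsAsFactors = FALSE
  )
  panel <- nppa_panel()
  if (k != nrow(panel))   # non-default panel size: synthetic site labels
    panel <- data.frame(label = paste0("CpG", seq_len(k)), chrom = "chrSim",
                        position = seq_len(k) * 10L, strand = "+",
                        tss_offset = seq_len(k) * 10L,
                        stringsAsFactors = FALSE)
  mm <- methylation_matrix(meth, panel, sample_ids)
  structure(list(phenotypes = phen, methylation = mm, truth = config),
            class = "Cohort")
}

## Cholesky tolerant of semi-definite matrices (e.g. identical CpGs)
chol_psd <- function(m) {
  r <- tryCatch(chol(m), error = function(e) NULL)
  if (!is.null(r)) return(r)
  e <- eigen(m, symmetric = TRUE)
  v <- pmax(e$values, 0)
  t(e$vectors %*% (t(e$vectors) * sqrt(v)))
}

#' @export
print.Cohort <- function(x, ...) {
  cat(sprintf("Cohort: %d samples, %d CpGs, %d (%.1f%%) hypertensive\n",
              nrow(x$phenotypes), ncol(x$methylation$values),
              sum(x$phenotypes$hypertension),
              100 * mean(x$phenotypes$hypertension)))
  invisible(x)
}

#' Read-count model for the sequencing layer
#'
#' @param mean_coverage Mean total reads per site (negative binomial).
#' @param coverage_dispersion Negative-binomial size parameter; larger
#'   values approach Poisson depth.
#' @param conversion_rate Bisulfite conversion efficiency in (0, 1];
#'   scalar or one value per sample. Incomplete conversion makes a
#'   fraction (1 - rate) of unmethylated cytosines read as methylated.
#' @return A `ReadCountModel` list.
#' @export
read_count_model <- function(mean_coverage = 100, coverage_dispersion = 8,
                             conversion_rate = 0.995) {
  if (mean_coverage <= 0) stop2("mean_coverage must be positive")
  if (coverage_dispersion <= 0) stop2("coverage_dispersion must be positive")
  if (any(conversion_rate <= 0 | conversion_rate > 1))
    stop2("conversion_rate must lie in (0, 1]")
  structure(list(mean_coverage = mean_coverage,
                 coverage_dispersion = coverage_dispersion,
                 conversion_rate = conversion_rate),
            class = "ReadCountModel")
}

#' Simulate bisulfite read counts for a cohort
#'
#' Total depth per (sample, site) is negative binomial; the methylated
#' count is binomial with success probability pi = m/100 + (1 - m/100) *
#' (1 - conversion_rate): conversion failures inflate apparent
#' methylation, which is what the conversion-rate QC threshold guards
#' against.
#'
#' @param cohort A [generate_cohort()] result.
#' @param model A [read_count_model()].
#' @return List of per-sample data.frames in Bismark coverage layout
#'   (chrom, start, end, methylation percent, methylated count,
#'   unmethylated count), with a `conversion_rate` attribute per the
#'   manifest.
#' @export
generate_read_counts <- function(cohort, model = read_count_model()) {
  stopifnot(inherits(cohort, "Cohort"), inherits(model, "ReadCountModel"))
  meth <- cohort$methylation$values
  sites <- cohort$methylation$sites
  n <- nrow(meth); k <- ncol(meth)
  conv <- rep(model$conversion_rate, length.out = n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    total <- rnbinom(k, mu = model$mean_coverage,
                     size = model$coverage_dispersion)
    pi <- meth[i, ] / 100 + (1 - meth[i, ] / 100) * (1 - conv[i])
    m <- rbinom(k, total, pi)
    out[[i]] <- data.frame(
      chrom = sites$chrom, start = sites$position, end = sites$position,
      pct = methylation_percent(m, total - m),
      count_m = m, count_u = total - m, stringsAsFactors = FALSE
    )
  }
  names(out) <- cohort$methylation$sample_ids
  attr(out, "conversion_rate") <- setNames(conv, names(out))
  out
}

#' Write a cohort to disk as phenotype TSV plus coverage files
#'
#' Emits `phenotypes.tsv`, one Bismark-dialect coverage file per sample
#' under `coverage/`, and `manifest.tsv` (sample_id, file,
#' conversion_rate) suitable for [read_coverage_files()].
#'
#' @param cohort A `Cohort`.
#' @param dir Output directory (created if needed).
#' @param counts Optional [generate_read_counts()] output; generated with
#'   `model` when `NULL`.
#' @param model Read-count model used when `counts` is `NULL`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, counts = NULL,
                         model = read_count_model()) {
  dir.create(file.path(dir, "coverage"), recursive = TRUE,
             showWarnings = FALSE)
  write.table(cohort$phenotypes, file.path(dir, "phenotypes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (is.null(counts)) counts <- generate_read_counts(cohort, model)
  conv <- attr(counts, "conversion_rate")
  files <- character(length(counts))
  for (i in seq_along(counts)) {
    files[i] <- file.path("coverage", paste0(names(counts)[i], ".cov"))
    write.table(counts[[i]], file.path(dir, files[i]), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  manifest <- data.frame(sample_id = names(counts), file = files,
                         conversion_rate = conv, stringsAsFactors = FALSE)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
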