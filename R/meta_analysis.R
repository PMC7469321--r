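## Fixed-effect and DerSimonian-Laird random-effects pooling of per-CpG
## effect estimates across the discovery and replication samples.

meta_result <- function(pooled_beta, pooled_se, Q, tau2, df, model,
                        labels) {
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  structure(list(
    pooled_beta = pooled_beta, pooled_se = pooled_se,
    p = 2 * pnorm(-abs(pooled_beta / pooled_se)),
    Q = Q, tau2 = tau2, I2 = I2, df = df, model = model,
    studies = labels
  ), class = "MetaResult")
}

#' @export
print.MetaResult <- function(x, ...) {
  cat(sprintf(
    "%s-effect meta-analysis of %d studies: beta = %.4f (SE %.4f), p = %.3g\n",
    x$model, length(x$studies), x$pooled_beta, x$pooled_se, x$p))
  cat(sprintf("  Q = %.3f (df %d), tau2 = %.4f, I2 = %.1f%%\n",
              x$Q, x$df, x$tau2, x$I2))
  invisible(x)
}

check_effects <- function(beta, se) {
  if (length(beta) != length(se)) stop2("beta and se lengths differ")
  if (length(beta) < 1L) stop2("need at least one study")
  if (any(se <= 0)) stop2("standard errors must be positive")
}

#' Fixed-effect (inverse-variance) meta-analysis
#'
#' @param beta Per-study effect estimates (here: per 5% methylation).
#' @param se Per-study standard errors (> 0).
#' @param labels Optional study labels.
#' @return A `MetaResult`.
#' @export
fixed_effect <- function(beta, se, labels = NULL) {
  check_effects(beta, se)
  w <- 1 / se^2
  pooled <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - pooled)^2)
  meta_result(pooled, 1 / sqrt(sum(w)), Q, 0, length(beta) - 1L,
              "fixed", labels %||% paste0("study", seq_along(beta)))
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Method-of-moments between-study variance
#' `tau2 = max(0, (Q - df) / C)` with `C = sum(w) - sum(w^2)/sum(w)` from
#' the fixed-effect weights `w = 1/se^2`, then inverse-variance pooling
#' with weights `1/(se^2 + tau2)` and a normal-reference p-value (note:
#' optimistic for two studies; no Knapp-Hartung adjustment).
#'
#' @inheritParams fixed_effect
#' @return A `MetaResult` (model `"random"`); its pooled SE is never
#'   smaller than the fixed-effect pooled SE.
#' @export
dersimonian_laird <- function(beta, se, labels = NULL) {
  check_effects(beta, se)
  if (length(beta) < 2L)
    stop2("random-effects pooling needs at least two studies")
  w <- 1 / se^2
  fixed <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - fixed)^2)
  df <- length(beta) - 1L
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - df) / C)
  wr <- 1 / (se^2 + tau2)
  meta_result(sum(wr * beta) / sum(wr), 1 / sqrt(sum(wr)), Q, tau2, df,
              "random", labels %||% paste0("study", seq_along(beta)))
}

#' Meta-analyze two association tables
#'
#' Joins two [associate_all()] tables by site and outcome and pools each
#' pair with both models.
#'
#' @param assoc1,assoc2 `AssocResult` data.frames (e.g. discovery and
#'   replication).
#' @param labels Length-2 study labels.
#' @return data.frame: site, outcome, model, pooled_beta, pooled_se, p,
#'   Q, tau2, I2.
#' @export
meta_analyze <- function(assoc1, assoc2,
                         labels = c("discovery", "replication")) {
  key1 <- paste(assoc1$site, assoc1$outcome)
  key2 <- paste(assoc2$site, assoc2$outcome)
  common <- intersect(key1, key2)
  rows <- lapply(common, function(k) {
    r1 <- assoc1[key1 == k, ][1, ]
    r2 <- assoc2[key2 == k, ][1, ]
    do.call(rbind, lapply(list(
      fixed_effect(c(r1$beta_per5, r2$beta_per5), c(r1$se, r2$se), labels),
      dersimonian_laird(c(r1$beta_per5, r2$beta_per5), c(r1$se, r2$se),
                        labels)
    ), function(m) data.frame(
      site = r1$site, outcome = r1$outcome, model = m$model,
      pooled_beta = m$pooled_beta, pooled_se = m$pooled_se, p = m$p,
      Q = m$Q, tau2 = m$tau2, I2 = m$I2, stringsAsFactors = FALSE
    )))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
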