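---
title: "Methods: methylation–blood-pressure association in methbp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation–blood-pressure association in methbp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the models and their assumptions, the tunable parameters and
their defaults, what the synthetic-cohort generator does and does not
emulate, and the design decisions taken where the methodology was
genuinely open. It states no empirical result that the test suite does
not itself compute.

## 1. Quantification and quality control

Targeted bisulfite sequencing reports, per sample and CpG cytosine, a
methylated read count $M$ and an unmethylated count $U$; the methylation
level is the percentage $100\,M/(M+U)$, undefined (masked) at zero
coverage. Two QC rules act in a fixed, logged order:

* **samples first** — a sample is removed when its bisulfite conversion
  rate is below 0.98. Incomplete conversion leaves unmethylated cytosines
  reading as methylated, inflating every percentage for that sample, so
  the filter is per sample, not per site. The boundary is kept: the
  removal condition is strict (`< 98%`).
* **sites second** — a site is removed when its mean coverage across the
  *retained* samples is below 20×. Again the boundary (exactly 20×) is
  kept. Cells that survive the site-level filter are not additionally
  masked by per-cell depth; whether the original study masked individual
  low-coverage cells is not documented, and the site-level rule is the
  stated one.

Percentages are always recomputed from the counts; column 4 of a
coverage file is never trusted.

**Coordinates.** The bundled panel lists nine CpGs on the minus strand of
GRCh37 chromosome 1. The TSS coordinate 11907840 is *back-derived*: it is
the unique constant for which `tss − position` reproduces every published
(position, TSS-offset) pair and both end points of the assayed window
(11908117 → −277, 11908380 → −540). Public TSS annotations differ by a
few bases; internal consistency of the panel was preferred over any
external annotation, and the constant lives in one place
(`nppa_panel()`, and the `# tss_coordinate:` header of the shipped panel
file) so position and offset cannot drift apart.

## 2. Single-CpG models

For CpG $j$ with methylation $m_{ij}$ (percent) in individual $i$:

* **continuous outcomes** (SBP, DBP, mmHg): OLS of the outcome on
  $m_{ij}/5$ plus covariates. The coefficient is the blood-pressure
  change per 5-percentage-point methylation increase; its p-value is the
  Wald $t$ test.
* **binary outcome** (prevalent hypertension: SBP ≥ 140 and/or DBP ≥ 90,
  or current antihypertensive treatment): maximum-likelihood logistic
  regression (IRLS, convergence tolerance $10^{-8}$, at most 100
  iterations) on the same per-5 scale; OR $=e^{\beta}$ with Wald 95% CI
  and normal-reference p-value.

Covariates are age, sex, education (≥ high school), current smoking,
current drinking, BMI, fasting glucose, LDL-C and HDL-C; the BP models
additionally adjust for antihypertensive medication, the hypertension
model must not (treatment is part of the case definition). Binary
covariates are coded 0/1, continuous ones untransformed. Analyses are
complete-case with `n_used` reported; no imputation is attempted.

Degenerate designs fail loudly: rank-deficient model matrices report the
offending columns; a scaled condition number above $10^{10}$ is an error;
logistic fits that fail to converge, or converge with a diverging
methylation coefficient ($|\beta| > 15$ on the per-5 log-odds scale),
are reported as suspected separation rather than returned.

**Descriptive comparisons** use the pooled-variance Student $t$ test
(from raw data or from printed $n$/mean/SD) and the uncorrected Pearson
chi-square on 2×2 tables. Pooled rather than Welch variance was chosen
because the source analyses name Student's test and the group SDs are
nearly equal; at the published group sizes the distinction is far below
the printed precision.

## 3. Multiple testing

Benjamini–Hochberg step-up q-values are computed within one family per
outcome per sample — the $m = 9$ CpGs tested — via
$q_{(i)} = \min_{j \ge i} p_{(j)}\, m/j$ with a stable sort for ties.
Gene-based p-values are not FDR-corrected (they are single tests of one
region). When reproducing published tables whose smallest entries are
censored as "< 0.001", those entries are represented by any stand-in
strictly below the smallest uncensored p-value; the q-values asserted in
the tests are invariant to that choice, and the test suite proves it by
trying several stand-ins.

## 4. Gene-based tests

Neighbouring CpGs are strongly co-methylated, so the panel is also tested
as a unit, two ways.

**Average methylation.** The per-sample mean over unmasked CpGs is fed to
the same single-CpG models unchanged.

**Weighted truncated product method (wTPM).** With per-CpG p-values
$p_j$ and adjusted coefficients $b_j$, truncation threshold $\tau = 0.1$,
and inclusion set $S = \{j : p_j \le \tau\}$:

$$W \;=\; \prod_{j \in S} p_j^{\,w_j}, \qquad
  w_j \;=\; \frac{|b_j|}{\sum_{k \in S} |b_k|}.$$

The source description says only that coefficients are "included as
weights"; exponent weighting with normalized $|b_j|$ is the standard
weighted-product form, reduces to the plain truncated product (TPM,
$W = \prod_{S} p_j$) under equal weights, and keeps $W \in (0,1]$. When
nothing is included $W = 1$ and the combined p-value is 1 (no evidence to
combine); when all included coefficients are exactly zero, equal weights
are substituted with a warning.

**Null calibration.** Because the $p_j$ are correlated, significance of
$W$ comes from permutation:

* *continuous outcomes* — Freedman–Lane: the outcome is regressed on the
  covariates alone; each permutation rebuilds it as fitted values plus
  permuted residuals and recomputes every per-CpG statistic. The
  implementation uses Frisch–Waugh–Lovell algebra (outcome and
  methylation residualized on the covariate span once, then matrix
  products per permutation), which is *exactly* the per-CpG OLS fit —
  the tests verify agreement with `lm()` to 1e-10 — and makes 500-replicate
  calibration studies feasible on one CPU.
* *binary outcome* — the methylation columns are residualized on the
  covariates under the null model's IRLS weights and permuted jointly as
  rows, preserving the CpG correlation; per-CpG Rao score statistics with
  the null-model variance (held fixed across permutations) are used for
  both the observed and permuted draws. This is the standard fast
  approximation; Wald and score p-values are near-identical at these
  effect sizes, and the user-facing association tables still report the
  full Wald fits.

The combined p-value uses the add-one rule $(1 + \#\{W^* \le W\})/(B+1)$
so it can never be zero; the default is $B = 9999$ and a seed is
required (one is generated and reported if omitted). Note the statistic
has an atom at $W = 1$: the permutation p-value is valid (sub-uniform)
everywhere but conservative near 1.

**Independent-case oracle.** For $L$ independent uniform p-values the
null CDF of the *unweighted* truncated product is closed-form:

$$\Pr(W^* \le w) = \sum_{k=1}^{L} \binom{L}{k} (1-\tau)^{L-k}
  \Big[ \mathbb{1}(w \le \tau^k)\, w \sum_{s=0}^{k-1}
  \frac{(k\ln\tau - \ln w)^s}{s!} + \mathbb{1}(w > \tau^k)\,\tau^k \Big],$$

implemented in log space (`tpm_pvalue_independent()`). It is *not* used
for inference on correlated CpGs; it validates the permutation machinery:
with an identity CpG correlation and `statistic = "tpm"`, the permutation
p-value matches it within Monte-Carlo error. The weighted statistic with
data-driven weights has no closed form even under independence — and
because the geometric-mean form ranks differently across inclusion
counts, wTPM and TPM are rank-equivalent only at a fixed inclusion count,
which is exactly what the test suite asserts.

## 5. Meta-analysis

Per-CpG estimates from two samples are pooled by inverse variance
(fixed effect) and by DerSimonian–Laird: $Q$ from the fixed-effect
weights, $\tau^2 = \max(0, (Q - df)/C)$ with
$C = \sum w - \sum w^2 / \sum w$, random weights $1/(se^2 + \tau^2)$, and
a normal-reference p-value. DL is the conventional estimator for a
two-study epidemiological meta-analysis; the normal reference (rather
than Knapp–Hartung) matches that convention but is optimistic with two
studies — the random-effects pooled SE is still never below the
fixed-effect SE, which the tests assert as an invariant.

## 6. The synthetic-cohort generator

The generator's defaults *are* the stated world of a discovery-scale
sample; they are not tuning knobs.

* **Methylation:** latent Gaussian copula — $Z \sim N(0, R)$ with unit
  diagonal, scaled per CpG to the target mean and SD, clipped to
  $[0,100]$. Means (29.0 … 93.3%) and SDs (2.5 … 7.6%) follow the
  normotensive column of the published methylation table. Clipping, not
  resampling, preserves seed alignment; at these means/SDs it affects a
  negligible sliver of draws. No CpG–CpG correlation values are
  published, so the default $R$ is AR(1) with $\rho = 0.7$ — a stand-in
  for the reported "highly correlated neighbours", exposed in the config
  precisely because it is a stand-in.
* **Covariates:** moments of the pooled discovery sample (age 52.7 ± 9.5,
  38.5% men, BMI 24.8 ± 3.6, …); binary covariates Bernoulli, continuous
  Gaussian, mutually independent — a simplification (real risk factors
  co-vary), acceptable because downstream inference conditions on them.
* **Blood pressure:** linear in centered covariates and centered
  methylation per 5, plus Gaussian noise (SD 15/10 mmHg for SBP/DBP);
  intercepts 130/82 mmHg give ≈ 43–45% prevalence under the clinical
  rule, matching the discovery sample. Default methylation effects are
  the published discovery per-5% coefficients (≈ −1 mmHg at the
  strongest CpG).
* **Hypertension — an open design point.** The artifact must satisfy two
  requirements that no single mechanism can: the case flag must equal the
  clinical rule applied to the generated data, *and* a configured log-OR
  per 5% methylation must be recoverable by logistic regression. The
  resolution is two modes. In *threshold* mode (default) the flag is
  derived from generated BP plus a treatment flag assigned among
  BP-defined cases. In *logistic* mode (auto-selected when any
  `logor_htn_per5` is non-zero) the flag is drawn from the logistic
  model, and BP/treatment are then minimally reconciled: cases below
  both thresholds are marked treated ("controlled on medication"),
  controls above a threshold are clamped just below it. The clinical
  rule reproduces the flag exactly in both modes; linear-effect recovery
  is exact only in threshold mode, OR recovery only in logistic mode,
  and the tests use each mode for its own question.
* **Read counts:** depth per cell is negative binomial (default mean
  100×, size 8 — realistic overdispersion for amplicon sequencing);
  methylated counts are binomial with success probability
  $m/100 + (1 - m/100)(1 - c)$ for conversion rate $c$, so incomplete
  conversion inflates apparent methylation exactly as the QC threshold
  assumes.

**What a green test does not establish.** The generator emulates the
*statistical* structure only: no cell-type composition effects, no batch
or plate structure, no genotype–methylation dependence, no non-Gaussian
methylation marginals (real percent data near 0/100 are beta-like), no
missingness mechanism beyond coverage, and no case–control sampling of
the kind that produced the older, stroke-enriched replication sample.
Passing recovery and calibration tests on this world shows the estimators
and their nulls are correct, not that the pipeline is robust to those
real-data complications.

## 7. Numerical and reproducibility choices

* IRLS tolerance $10^{-8}$, max 100 iterations; condition-number guard
  $10^{10}$ on the scaled design.
* BH uses a stable sort; censored published p-values are represented as
  5×10⁻⁴ where a number is needed, with all asserted targets invariant
  to the representation.
* Permutation counting uses $W^* \le W + 10^{-15}$ to make ties
  deterministic across platforms.
* Every stochastic entry point takes an explicit integer seed; pipeline
  outputs are stamped with a 32-bit FNV-1a hash of the analysis-relevant
  config (output paths excluded) plus the seed, and reruns are
  byte-identical apart from log timestamps.
* Heavy validation (closed form vs 2×10⁶-draw Monte Carlo; 500-cohort
  permutation calibration at $B = 499$, $n = 500$) runs inside the test
  suite in a few minutes thanks to the vectorized permutation algebra.

## 8. Known limitations

Cross-sectional associations only (no causal claims); no mixed models,
interactions or stratified analyses; no Storey q-values or
permutation-based FDR; the wTPM weighting and null are explicit,
documented substitutes for an under-specified published procedure; meta
p-values with two studies are optimistic by construction; and the
independent-case closed form must never be used for inference on
co-methylated panels.
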