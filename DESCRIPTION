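Package: methbp
Title: Targeted Bisulfite Methylation Association Analysis for Blood
    Pressure and Hypertension
Version: 0.1.0
Authors@R: person("Gusu", "Analytics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for targeted bisulfite
    sequencing studies of promoter DNA methylation and blood pressure.
    Provides per-CpG methylation quantification from Bismark-style
    coverage files with conversion-rate and depth quality control,
    covariate-adjusted single-CpG linear and logistic association models
    scaled per 5 percent methylation, Benjamini-Hochberg false discovery
    rate control, gene-based tests (mean methylation and the weighted
    truncated product method with a permutation null), DerSimonian-Laird
    random-effects meta-analysis across samples, and a synthetic-cohort
    generator that emulates the statistical structure of a two-sample
    epigenetic association study of hypertension.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
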