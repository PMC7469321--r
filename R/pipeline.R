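## Configuration-driven end-to-end driver: QC -> methylation matrix ->
## group comparison -> single-CpG association with FDR -> gene-based
## tests -> optional two-sample meta-analysis, with deterministic,
## config-hash-stamped TSV outputs.

#' Load and validate a run configuration
#'
#' @param config A YAML file path or a list. Recognized fields: `seed`
#'   (required), `outdir`, `tau`, `B`, `qc` (list: `conversion_threshold`,
#'   `min_mean_coverage`), and exactly one of `simulate` (a list of
#'   [cohort_config()] overrides, plus optional `read_counts: true` to
#'   exercise the coverage-file layer) or `inputs` (list: `manifest`,
#'   `phenotypes`, optional `panel`); optional `meta`: two association
#'   TSV paths to pool.
#' @return Validated config list with defaults filled in.
#' @export
load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop2("config must set a seed")
  config$seed <- as.integer(config$seed)
  config$tau <- config$tau %||% 0.1
  if (config$tau <= 0 || config$tau > 1) stop2("tau must lie in (0, 1]")
  config$B <- as.integer(config$B %||% 9999)
  config$qc <- config$qc %||% list()
  config$qc$conversion_threshold <- config$qc$conversion_threshold %||% 0.98
  config$qc$min_mean_coverage <- config$qc$min_mean_coverage %||% 20
  if (is.null(config$simulate) == is.null(config$inputs))
    stop2("config must set exactly one of 'simulate' or 'inputs'")
  config
}

stamp_write <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s\tseed: %d", hash, seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Read a pipeline output table (skipping the config-hash stamp)
#'
#' @param path Table path.
#' @return data.frame.
#' @export
read_stamped <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Group-comparison table (per-CpG means by hypertension status)
#'
#' Mean and SD of each CpG and of the panel average by case status, the
#' pooled-variance t-test p-value, and BH q-values over the CpG family
#' (the average row, being a summary of the family, is not part of it).
#'
#' @param mm A `MethylationMatrix`.
#' @param phenotypes Phenotype data.frame with a `hypertension` column.
#' @return data.frame: site, n_non_hbp, n_hbp, mean_non_hbp, sd_non_hbp,
#'   mean_hbp, sd_hbp, p, q.
#' @export
group_comparison <- function(mm, phenotypes) {
  grp <- phenotypes$hypertension == 1
  vals <- cbind(mm$values, Average = average_methylation(mm))
  rows <- lapply(colnames(vals), function(lab) {
    v <- vals[, lab]
    v0 <- v[!grp & !is.na(v)]; v1 <- v[grp & !is.na(v)]
    tt <- two_sample_t_summary(length(v0), mean(v0), sd(v0),
                               length(v1), mean(v1), sd(v1))
    data.frame(site = lab, n_non_hbp = length(v0), n_hbp = length(v1),
               mean_non_hbp = mean(v0), sd_non_hbp = sd(v0),
               mean_hbp = mean(v1), sd_hbp = sd(v1), p = tt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  cpg <- out$site != "Average"
  out$q <- NA_real_
  out$q[cpg] <- bh_qvalues(out$p[cpg])
  out
}

#' Run the full analysis pipeline
#'
#' Stages: obtain the cohort (simulated, or coverage files + phenotypes
#' through QC), write the methylation matrix and QC report, group
#' comparison, single-CpG association for SBP/DBP/hypertension with BH
#' q-values, gene-based tests (average + wTPM), and optionally a
#' two-sample meta-analysis. All tables are stamped with the config hash
#' and seed; a rerun with the same config is identical except the log's
#' timestamps. On a stage failure, files already written by this run are
#' removed and the error names the stage.
#'
#' @param config Config list or YAML path (see [load_run_config()]).
#' @param outdir,seed Optional overrides of the config fields.
#' @return Invisible list of the in-memory tables
#'   (`group_comparison`, `association`, `gene_based`, `meta`) plus
#'   `outdir` and `files`.
#' @export
run_pipeline <- function(config, outdir = NULL, seed = NULL) {
  config <- load_run_config(config)
  if (!is.null(outdir)) config$outdir <- outdir
  if (!is.null(seed)) config$seed <- as.integer(seed)
  outdir <- config$outdir %||% stop2("config must set outdir")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ## hash the analysis-relevant configuration only, so the same analysis
  ## written to a different directory carries the same fingerprint
  hash <- config_hash(config[setdiff(names(config), c("outdir", "meta"))])
  written <- character(0)
  logf <- file.path(outdir, "run.log")
  log_line <- function(...) cat(sprintf("[%s] %s\n",
                                        format(Sys.time(), "%H:%M:%S"),
                                        sprintf(...)),
                                file = logf, append = TRUE)
  emit <- function(df, name) {
    p <- stamp_write(df, file.path(outdir, name), hash, config$seed)
    written <<- c(written, p)
    p
  }
  stage <- function(name, expr) {
    log_line("stage %s: start", name)
    out <- tryCatch(expr, error = function(e) {
      unlink(written)
      stop2("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    log_line("stage %s: done", name)
    out
  }
  cat(sprintf("# run config_hash: %s seed: %d\n", hash, config$seed),
      file = logf)

  cohort_bits <- stage("input", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      sim$read_counts <- NULL
      cc <- do.call(cohort_config,
                    c(sim[setdiff(names(sim), "seed")],
                      list(seed = config$seed)))
      cohort <- generate_cohort(cc)
      if (isTRUE(config$simulate$read_counts)) {
        simdir <- file.path(outdir, "simulated_input")
        write_cohort(cohort, simdir)
        mm <- read_coverage_files(
          file.path(simdir, "manifest.tsv"),
          conversion_threshold = config$qc$conversion_threshold,
          min_mean_coverage = config$qc$min_mean_coverage)
        phen <- cohort$phenotypes[
          cohort$phenotypes$sample_id %in% mm$sample_ids, ]
      } else {
        mm <- cohort$methylation
        phen <- cohort$phenotypes
      }
      list(mm = mm, phen = phen)
    } else {
      panel <- if (!is.null(config$inputs$panel))
        read_site_panel(config$inputs$panel) else nppa_panel()
      mm <- read_coverage_files(
        config$inputs$manifest, panel = panel,
        conversion_threshold = config$qc$conversion_threshold,
        min_mean_coverage = config$qc$min_mean_coverage)
      phen <- read.table(config$inputs$phenotypes, header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)
      phen <- phen[match(mm$sample_ids, phen$sample_id), ]
      list(mm = mm, phen = phen)
    }
  })
  mm <- cohort_bits$mm
  phen <- cohort_bits$phen

  stage("qc_report", {
    qc <- attr(mm, "qc")
    qdf <- data.frame(
      metric = c("n_samples_retained", "n_samples_excluded",
                 "n_sites_retained", "n_sites_dropped",
                 "off_panel_records", "conversion_threshold",
                 "min_mean_coverage"),
      value = c(length(mm$sample_ids),
                if (is.null(qc)) 0 else nrow(qc$excluded_samples),
                ncol(mm$values),
                if (is.null(qc)) 0 else length(qc$dropped_sites),
                if (is.null(qc)) 0 else qc$off_panel_records,
                config$qc$conversion_threshold,
                config$qc$min_mean_coverage),
      stringsAsFactors = FALSE
    )
    emit(qdf, "qc_report.tsv")
    emit(data.frame(sample_id = mm$sample_ids,
                    round(mm$values, 6), check.names = FALSE),
         "methylation_matrix.tsv")
  })

  gc_tab <- stage("group_comparison",
                  emit(group_comparison(mm, phen), "group_comparison.tsv"))
  gc_tab <- read_stamped(gc_tab)

  assoc <- stage("association", {
    a <- associate_all(mm, phen)
    for (oc in unique(a$outcome))
      emit(a[a$outcome == oc, ], sprintf("association_%s.tsv", oc))
    a
  })

  gene <- stage("gene_based", {
    g <- gene_based_tests(mm, phen, tau = config$tau, B = config$B,
                          seed = config$seed)
    emit(g, "gene_based.tsv")
    g
  })

  meta <- NULL
  if (!is.null(config$meta)) {
    meta <- stage("meta", {
      missing_in <- config$meta[!file.exists(unlist(config$meta))]
      if (length(missing_in))
        stop2("association table(s) not found: %s",
              paste(missing_in, collapse = ", "))
      a1 <- read_stamped(config$meta[[1]])
      a2 <- read_stamped(config$meta[[2]])
      m <- meta_analyze(a1, a2)
      emit(m, "meta.tsv")
      m
    })
  }

  log_line("pipeline complete: %d tables", length(written))
  invisible(list(group_comparison = gc_tab, association = assoc,
                 gene_based = gene, meta = meta, outdir = outdir,
                 files = written, config_hash = hash))
}

#' Command-line entry point
#'
#' Subcommands: `simulate` writes a synthetic cohort (phenotype TSV,
#' coverage files, manifest) to the output directory; `qc`, `associate`,
#' `genetest`, `meta` and `all` run the pipeline (stages are cheap and
#' internally ordered, so they share one driver; `meta` requires the
#' `meta:` config field). Options: `--config` (required), `--outdir`,
#' `--seed`.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status, invisibly: 0 on success, 2 on a
#'   validation or usage error.
#' @export
methbp_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  sub <- if (length(args)) args[[1]] else ""
  known <- c("simulate", "qc", "associate", "genetest", "meta", "all")
  if (!sub %in% known) {
    message("usage: methbp <", paste(known, collapse = "|"),
            "> --config FILE [--outdir DIR] [--seed N]")
    return(invisible(2L))
  }
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character"),
    optparse::make_option("--outdir", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL)
  ))
  opt <- tryCatch(optparse::parse_args(parser, args[-1]),
                  error = function(e) NULL)
  if (is.null(opt) || is.null(opt$config)) {
    message("a --config file is required")
    return(invisible(2L))
  }
  status <- tryCatch({
    if (sub == "simulate") {
      config <- load_run_config(opt$config)
      if (!is.null(opt$seed)) config$seed <- opt$seed
      if (is.null(config$simulate))
        stop2("'simulate' needs a config with a simulate block")
      sim <- config$simulate
      sim$read_counts <- NULL
      cc <- do.call(cohort_config,
                    c(sim[setdiff(names(sim), "seed")],
                      list(seed = config$seed)))
      write_cohort(generate_cohort(cc),
                   opt$outdir %||% config$outdir %||% ".")
    } else {
      run_pipeline(opt$config, outdir = opt$outdir, seed = opt$seed)
    }
    0L
  }, error = function(e) {
    message(conditionMessage(e))
    2L
  })
  invisible(status)
}
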