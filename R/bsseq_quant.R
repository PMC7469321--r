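## Quantification of targeted bisulfite read counts into a QC-filtered
## samples x CpG methylation matrix, with GRCh37 / TSS-relative coordinate
## bookkeeping for the bundled NPPA promoter panel.

#' Signed distance of a genomic position from a transcription start site
#'
#' For a gene on the minus strand the promoter lies at coordinates larger
#' than the TSS, so the TSS-relative offset of an upstream position is
#' `tss - position` (negative upstream). On the plus strand it is
#' `position - tss`.
#'
#' @param position 1-based genomic coordinate(s).
#' @param tss_coordinate 1-based TSS coordinate.
#' @param strand `"+"` or `"-"`.
#' @return Signed offset(s) in bp, negative upstream of the TSS.
#' @examples
#' tss_offset(11908353, 11907840, "-")  # -513
#' @export
tss_offset <- function(position, tss_coordinate, strand) {
  if (any(position <= 0) || any(tss_coordinate <= 0))
    stop2("coordinates must be positive")
  if (length(strand) != 1L || !strand %in% c("+", "-"))
    stop2("strand must be \"+\" or \"-\", got %s", deparse(strand))
  if (strand == "-") tss_coordinate - position else position - tss_coordinate
}

#' The bundled NPPA promoter CpG panel
#'
#' Nine CpG sites in the NPPA promoter (GRCh37 Chr1:11908117-11908380,
#' minus strand; assayed window -540 to -277 bp from the TSS at
#' Chr1:11907840). Offsets are derived from the single TSS constant, not
#' stored, so position and offset cannot drift apart.
#'
#' @return A data.frame with columns `label`, `chrom`, `position`,
#'   `strand`, `tss_offset`, plus attribute `tss_coordinate`.
#' @export
nppa_panel <- function() {
  tss <- 11907840
  pos <- c(11908353, 11908348, 11908299, 11908200, 11908182,
           11908178, 11908168, 11908165, 11908142)
  panel <- data.frame(
    label = paste0("CpG", seq_along(pos)),
    chrom = "Chr1",
    position = pos,
    strand = "-",
    tss_offset = tss_offset(pos, tss, "-"),
    stringsAsFactors = FALSE
  )
  attr(panel, "tss_coordinate") <- tss
  panel
}

#' Read a site panel from a BED-like TSV
#'
#' Expects tab-separated columns chrom, start, end, label, strand (1-based
#' inclusive start = end for a CpG cytosine) preceded by comment lines of
#' the form `# key: value`; the key `tss_coordinate` is required.
#'
#' @param path Path to the panel file.
#' @return A panel data.frame as from [nppa_panel()].
#' @export
read_site_panel <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(\\S+)", hdr))
  meta <- setNames(
    vapply(kv, function(m) if (length(m)) m[3] else NA_character_, ""),
    vapply(kv, function(m) if (length(m)) m[2] else NA_character_, "")
  )
  if (!"tss_coordinate" %in% names(meta))
    stop2("site panel %s lacks a '# tss_coordinate:' header", path)
  tss <- as.numeric(meta[["tss_coordinate"]])
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  df <- read.table(text = body, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "label", "strand"))
  if (any(df$start != df$end))
    stop2("site panel rows must have start == end (one cytosine per row)")
  strand <- unique(df$strand)
  if (length(strand) != 1L) stop2("site panel mixes strands")
  panel <- data.frame(
    label = df$label, chrom = df$chrom, position = df$start,
    strand = df$strand,
    tss_offset = tss_offset(df$start, tss, strand),
    stringsAsFactors = FALSE
  )
  attr(panel, "tss_coordinate") <- tss
  panel
}

#' Methylation percentage from read counts
#'
#' 100 * M / (M + U); `NA` where no reads cover the site.
#'
#' @param count_methylated,count_unmethylated Non-negative read counts
#'   (vectorized).
#' @return Percentages in \[0, 100\], `NA` at zero total coverage.
#' @export
methylation_percent <- function(count_methylated, count_unmethylated) {
  if (any(count_methylated < 0, na.rm = TRUE) ||
      any(count_unmethylated < 0, na.rm = TRUE))
    stop2("read counts must be non-negative")
  total <- count_methylated + count_unmethylated
  ifelse(total == 0, NA_real_, 100 * count_methylated / total)
}

#' Sample-level QC on bisulfite conversion rate
#'
#' Retains samples whose conversion rate is at or above `threshold`
#' (default 0.98: samples converting < 98% of unmethylated cytosines are
#' removed, the boundary is kept).
#'
#' @param manifest data.frame with columns `sample_id` and
#'   `conversion_rate` (rates in \[0, 1\]).
#' @param threshold Minimum acceptable conversion rate.
#' @return List with `retained` (sample ids) and `excluded`
#'   (data.frame sample_id, conversion_rate, reason).
#' @export
filter_samples <- function(manifest, threshold = 0.98) {
  if (nrow(manifest) == 0L) {
    warning("empty manifest: no samples to retain")
    return(list(retained = character(0),
                excluded = data.frame(sample_id = character(0),
                                      conversion_rate = numeric(0),
                                      reason = character(0))))
  }
  rate <- manifest$conversion_rate
  if (any(rate < 0 | rate > 1))
    stop2("conversion rates must lie in [0, 1]")
  keep <- rate >= threshold
  excluded <- data.frame(
    sample_id = as.character(manifest$sample_id[!keep]),
    conversion_rate = rate[!keep],
    reason = sprintf("conversion rate %.4f < %.2f", rate[!keep], threshold),
    stringsAsFactors = FALSE
  )
  list(retained = as.character(manifest$sample_id[keep]), excluded = excluded)
}

#' Site-level QC on sequencing depth
#'
#' Retains sites whose mean coverage across the (already sample-filtered)
#' matrix is at least `min_mean_coverage` (default 20x; sites averaging
#' below 20x are removed, the boundary is kept).
#'
#' @param coverage Samples x sites matrix of total read counts.
#' @param min_mean_coverage Minimum mean depth.
#' @return Logical vector over sites (TRUE = keep).
#' @export
filter_sites <- function(coverage, min_mean_coverage = 20) {
  if (any(coverage < 0, na.rm = TRUE)) stop2("coverage must be non-negative")
  colMeans(coverage, na.rm = TRUE) >= min_mean_coverage
}

#' Construct a samples x CpG methylation matrix
#'
#' @param values Samples x sites matrix of methylation percent (`NA` =
#'   masked).
#' @param sites Site panel data.frame (see [nppa_panel()]).
#' @param sample_ids Character vector, one per row of `values`.
#' @param coverage Optional matching matrix of total read counts.
#' @return A `MethylationMatrix` object.
#' @export
methylation_matrix <- function(values, sites, sample_ids,
                               coverage = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != length(sample_ids))
    stop2("values has %d rows but %d sample ids", nrow(values),
          length(sample_ids))
  if (ncol(values) != nrow(sites))
    stop2("values has %d columns but %d panel sites", ncol(values),
          nrow(sites))
  if (any(values < 0 | values > 100, na.rm = TRUE))
    stop2("methylation percentages must lie in [0, 100]")
  if (!is.null(coverage) && !all(dim(coverage) == dim(values)))
    stop2("coverage dimensions do not match values")
  dimnames(values) <- list(sample_ids, sites$label)
  if (!is.null(coverage)) dimnames(coverage) <- dimnames(values)
  structure(list(values = values, coverage = coverage, sites = sites,
                 sample_ids = as.character(sample_ids)),
            class = "MethylationMatrix")
}

#' @export
print.MethylationMatrix <- function(x, ...) {
  cat(sprintf("MethylationMatrix: %d samples x %d CpG sites\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  sites: %s\n", paste(x$sites$label, collapse = ", ")))
  cat(sprintf("  masked cells: %d\n", sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.MethylationMatrix <- function(x) dim(x$values)

#' Assemble a methylation matrix from Bismark-style coverage files
#'
#' Reads per-sample coverage files (tab-separated chrom, start, end,
#' methylation percent, methylated count, unmethylated count; 1-based
#' inclusive, start = end per CpG cytosine), joins them to the site panel
#' by (chrom, position), then applies QC: samples failing the conversion
#' threshold are dropped first, then sites whose mean coverage over the
#' retained samples falls below the depth threshold. Percentages are
#' recomputed from counts, never trusted from column 4.
#'
#' @param manifest data.frame (or path to a TSV) with columns `sample_id`,
#'   `file`, `conversion_rate`; relative paths resolve against the
#'   manifest's directory.
#' @param panel Site panel (default the bundled NPPA panel).
#' @param conversion_threshold,min_mean_coverage QC thresholds.
#' @return A `MethylationMatrix` with attribute `qc` (list: excluded
#'   samples, dropped sites, ignored off-panel record count).
#' @export
read_coverage_files <- function(manifest, panel = nppa_panel(),
                                conversion_threshold = 0.98,
                                min_mean_coverage = 20) {
  base_dir <- "."
  if (is.character(manifest) && length(manifest) == 1L) {
    base_dir <- dirname(manifest)
    manifest <- read.table(manifest, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  }
  needed <- c("sample_id", "file", "conversion_rate")
  if (!all(needed %in% names(manifest)))
    stop2("manifest must have columns %s", paste(needed, collapse = ", "))

  qc_samples <- filter_samples(manifest, conversion_threshold)
  kept <- manifest[manifest$sample_id %in% qc_samples$retained, , drop = FALSE]

  n <- nrow(kept)
  meth <- matrix(NA_real_, n, nrow(panel))
  cov <- matrix(0, n, nrow(panel))
  key <- paste(panel$chrom, panel$position)
  ignored <- 0L
  for (i in seq_len(n)) {
    path <- kept$file[i]
    if (!file.exists(path)) path <- file.path(base_dir, kept$file[i])
    rec <- tryCatch(
      read.table(path, sep = "\t", stringsAsFactors = FALSE,
                 col.names = c("chrom", "start", "end", "pct",
                               "count_m", "count_u")),
      error = function(e) stop2("malformed coverage file %s: %s",
                                path, conditionMessage(e))
    )
    idx <- match(paste(rec$chrom, rec$start), key)
    ignored <- ignored + sum(is.na(idx))
    rec <- rec[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
    if (anyDuplicated(idx))
      stop2("duplicate record for sample %s at panel position(s) %s",
            kept$sample_id[i],
            paste(panel$position[idx[duplicated(idx)]], collapse = ", "))
    cov[i, idx] <- rec$count_m + rec$count_u
    meth[i, idx] <- methylation_percent(rec$count_m, rec$count_u)
  }

  keep_site <- filter_sites(cov, min_mean_coverage)
  mm <- methylation_matrix(meth[, keep_site, drop = FALSE],
                           panel[keep_site, , drop = FALSE],
                           kept$sample_id,
                           cov[, keep_site, drop = FALSE])
  attr(mm, "qc") <- list(
    excluded_samples = qc_samples$excluded,
    dropped_sites = panel$label[!keep_site],
    off_panel_records = ignored,
    conversion_threshold = conversion_threshold,
    min_mean_coverage = min_mean_coverage
  )
  mm
}
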