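# Marker and sample quality control applied before ROH calling:
# sample call rate, SNP call rate, minor allele frequency, and exact
# Hardy-Weinberg equilibrium in controls.

#' Remove samples with a low genotype call rate
#'
#' @param panel a [genotype_panel].
#' @param min_rate minimum fraction of non-missing calls a sample must
#'   have to be retained (default 0.95).
#' @return `list(panel, report)` where `report` is a [qc_report()].
#' @export
filter_samples_by_call_rate <- function(panel, min_rate = 0.95) {
  stopifnot(n_samples(panel) > 0)
  call_rate <- rowMeans(!is.na(panel$genotypes))
  drop <- call_rate < min_rate
  if (all(drop)) stop("empty panel: all samples removed by call-rate filter")
  removed <- data.frame(
    id = panel$samples$id[drop],
    reason = sprintf("call_rate %.4f < %.4f", call_rate[drop], min_rate),
    stringsAsFactors = FALSE
  )
  list(
    panel = panel[!drop, ],
    report = qc_report(samples_removed = removed,
                       thresholds = list(sample_call_rate_min = min_rate))
  )
}

#' Remove SNPs failing call-rate, MAF or Hardy-Weinberg filters
#'
#' A SNP is removed if its call rate is below `min_call_rate`, its minor
#' allele frequency (computed from non-missing calls of all samples) is
#' below `maf_min`, or its exact Hardy-Weinberg p-value -- evaluated in
#' controls only, so true case-enriched signals are not discarded -- is
#' below `hwe_alpha`. All three filters are evaluated on the input panel
#' and applied jointly.
#'
#' @param panel a [genotype_panel].
#' @param min_call_rate,maf_min,hwe_alpha thresholds (defaults 0.95,
#'   0.01, 1e-5).
#' @return `list(panel, report)`.
#' @export
filter_snps <- function(panel, min_call_rate = 0.95, maf_min = 0.01,
                        hwe_alpha = 1e-5) {
  stopifnot(n_variants(panel) > 0)
  g <- panel$genotypes
  call_rate <- colMeans(!is.na(g))
  n_called <- colSums(!is.na(g))
  freq_b <- colSums(g, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  maf <- pmin(freq_b, 1 - freq_b)
  maf[n_called == 0L] <- 0

  gc_ctrl <- g[panel$samples$phenotype == "control", , drop = FALSE]
  hwe_p <- vapply(seq_len(ncol(g)), function(j) {
    x <- gc_ctrl[, j]
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(1)
    hwe_exact_p(sum(x == 0L), sum(x == 1L), sum(x == 2L))
  }, 1)

  fail_cr <- call_rate < min_call_rate
  fail_maf <- maf < maf_min
  fail_hwe <- hwe_p < hwe_alpha
  drop <- fail_cr | fail_maf | fail_hwe
  if (all(drop)) stop("empty panel: all SNPs removed by marker QC")

  reason <- vapply(which(drop), function(j) {
    paste(c(
      if (fail_cr[j]) sprintf("call_rate %.4f", call_rate[j]),
      if (fail_maf[j]) sprintf("maf %.4g", maf[j]),
      if (fail_hwe[j]) sprintf("hwe_p %.3g", hwe_p[j])
    ), collapse = ";")
  }, "")
  removed <- data.frame(id = panel$variants$id[drop], reason = reason,
                        stringsAsFactors = FALSE)
  list(
    panel = panel[, !drop],
    report = qc_report(snps_removed = removed,
                       thresholds = list(snp_call_rate_min = min_call_rate,
                                         maf_min = maf_min,
                                         hwe_alpha = hwe_alpha))
  )
}

#' Apply full sample-then-marker QC
#'
#' Convenience wrapper: sample call-rate filter followed by the joint SNP
#' filters, with one merged report.
#'
#' @inheritParams filter_snps
#' @param sample_call_rate_min minimum per-sample call rate.
#' @return `list(panel, report)`.
#' @export
apply_qc <- function(panel, sample_call_rate_min = 0.95,
                     min_call_rate = 0.95, maf_min = 0.01,
                     hwe_alpha = 1e-5) {
  s1 <- filter_samples_by_call_rate(panel, sample_call_rate_min)
  s2 <- filter_snps(s1$panel, min_call_rate, maf_min, hwe_alpha)
  list(panel = s2$panel,
       report = qc_report(
         samples_removed = s1$report$samples_removed,
         snps_removed = s2$report$snps_removed,
         thresholds = c(s1$report$thresholds, s2$report$thresholds)
       ))
}

#' Construct a QC report
#'
#' @param samples_removed,snps_removed data.frames with `id` and `reason`.
#' @param thresholds named list of the thresholds applied.
#' @return A `qc_report` object.
#' @export
qc_report <- function(samples_removed = NULL, snps_removed = NULL,
                      thresholds = list()) {
  empty <- data.frame(id = character(), reason = character(),
                      stringsAsFactors = FALSE)
  structure(
    list(samples_removed = if (is.null(samples_removed)) empty else samples_removed,
         snps_removed = if (is.null(snps_removed)) empty else snps_removed,
         thresholds = thresholds),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:", nrow(x$samples_removed), "samples removed,",
      nrow(x$snps_removed), "SNPs removed\n")
  if (length(x$thresholds)) {
    cat("  thresholds:",
        paste(names(x$thresholds), unlist(x$thresholds), sep = "=",
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a QC report as a two-column summary TSV
#'
#' One row per filter with the count of items removed, mirroring the
#' per-dataset QC summary tables of array studies.
#'
#' @param report a [qc_report()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_qc_report <- function(report, path) {
  first_reason <- function(r) sub(" .*", "", sub(";.*", "", r))
  tab <- rbind(
    data.frame(filter = paste0("sample_",
                               first_reason(report$samples_removed$reason)),
               stringsAsFactors = FALSE),
    data.frame(filter = paste0("snp_",
                               first_reason(report$snps_removed$reason)),
               stringsAsFactors = FALSE)
  )
  counts <- as.data.frame(table(tab$filter), stringsAsFactors = FALSE)
  names(counts) <- c("filter", "n_removed")
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
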