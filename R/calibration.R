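# Cohort-specific minimum ROH length. The chance that L consecutive
# calls in one individual are all homozygous is (1-h)^L for mean
# heterozygosity h; across S SNPs and N individuals the expected number
# of chance runs is about (1-h)^L * S * N, and the minimum length is the
# smallest L pushing that expectation below alpha. Because SNPs are
# correlated through LD, the nominal length is then inflated by the ratio
# of total SNPs to separable tag groups obtained from pairwise r^2
# pruning.

#' Expected number of chance homozygous runs
#'
#' `(1 - h)^L * S * N`, evaluated in the log domain: the expected count
#' of length-`L` all-homozygous stretches arising by chance alone in a
#' panel of `S` SNPs and `N` individuals with mean heterozygosity `h`.
#'
#' @param h mean heterozygosity, in `(0, 1)`.
#' @param s_snps,n_samples panel dimensions.
#' @param run_length run length `L` (0 gives `S * N`).
#' @return Expected chance-run count.
#' @export
expected_chance_roh <- function(h, s_snps, n_samples, run_length) {
  if (h <= 0 || h >= 1) stop("domain error: h must be in (0, 1)")
  stopifnot(s_snps > 0, n_samples > 0, run_length >= 0)
  exp(run_length * log1p(-h) + log(s_snps) + log(n_samples))
}

#' Smallest run length with expected chance-run count below alpha
#'
#' Closed form `ceiling((log(alpha) - log(S) - log(N)) / log(1 - h))`,
#' verified and corrected by direct evaluation of
#' [expected_chance_roh()] at the boundary (the strict inequality can
#' shift the ceiling by one when the expectation lands exactly on
#' `alpha`).
#'
#' @inheritParams expected_chance_roh
#' @param alpha tolerated expected count of chance runs (default 0.05,
#'   i.e. fewer than 5% randomly generated ROH across all subjects).
#' @return Integer run length `L >= 1`.
#' @export
min_run_length <- function(h, s_snps, n_samples, alpha = 0.05) {
  if (h <= 0 || h >= 1) stop("domain error: h must be in (0, 1)")
  stopifnot(alpha > 0, alpha < 1)
  l <- max(1, ceiling((log(alpha) - log(s_snps) - log(n_samples)) /
                        log1p(-h)))
  while (expected_chance_roh(h, s_snps, n_samples, l) >= alpha) l <- l + 1
  while (l > 1 &&
         expected_chance_roh(h, s_snps, n_samples, l - 1) < alpha) l <- l - 1
  as.integer(l)
}

#' Count separable tag groups by pairwise LD pruning
#'
#' Greedy sliding-window pruning on genotype correlation: within each
#' window of retained SNPs, while any pair has `r^2` above the
#' threshold, the member of the worst (highest-`r^2`) pair with the
#' lower minor allele frequency is removed (tie broken against the later
#' map position); the window then advances by `step_snps`. The count of
#' retained SNPs estimates the number of separable tag groups, i.e. the
#' effective number of independent SNP calls.
#'
#' @param panel a QC'd [genotype_panel].
#' @param r2_threshold prune pairs with squared correlation above this
#'   (default 0.5).
#' @param window_snps,step_snps window size and step in SNPs (defaults
#'   50 and 5).
#' @return Integer count of retained SNPs (tag groups).
#' @export
count_tag_groups <- function(panel, r2_threshold = 0.5, window_snps = 50,
                             step_snps = 5) {
  blocks <- chrom_blocks(panel)
  g <- panel$genotypes
  n_called <- colSums(!is.na(g))
  freq_b <- colSums(g, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  maf <- pmin(freq_b, 1 - freq_b)
  keep <- rep(TRUE, ncol(g))
  for (bi in seq_len(nrow(blocks))) {
    cols <- blocks$start[bi]:blocks$end[bi]
    start <- 1L
    repeat {
      win <- cols[start:min(start + window_snps - 1L, length(cols))]
      win <- win[keep[win]]
      while (length(win) >= 2L) {
        r2 <- suppressWarnings(
          stats::cor(g[, win, drop = FALSE],
                     use = "pairwise.complete.obs")^2
        )
        r2[!is.finite(r2)] <- 0
        diag(r2) <- 0
        worst <- max(r2)
        if (worst <= r2_threshold) break
        pair <- which(r2 == worst, arr.ind = TRUE)[1, ]
        a <- win[pair[1]]
        b <- win[pair[2]]
        # drop the lower-MAF member; tie: the later map position
        drop <- if (maf[a] < maf[b]) a
                else if (maf[b] < maf[a]) b
                else max(a, b)
        keep[drop] <- FALSE
        win <- win[win != drop]
      }
      if (start + window_snps - 1L >= length(cols)) break
      start <- start + step_snps
    }
  }
  sum(keep)
}

#' Inflate a nominal run length for LD-induced redundancy
#'
#' `round(L_raw * S / T)` (round-half-even): the minimum length in
#' independent-SNP units is stretched by the information-reduction factor
#' `S / T`, where `T` of the `S` SNPs are separable tag groups, so the
#' adjusted segment length approximates the degrees of freedom of
#' `L_raw` independent calls.
#'
#' @param l_raw nominal minimum run length (independent-SNP units).
#' @param s_snps total SNP count `S`.
#' @param n_tag_groups tag-group count `T` from [count_tag_groups()].
#' @return Integer adjusted length, `>= l_raw`.
#' @export
ld_adjusted_length <- function(l_raw, s_snps, n_tag_groups) {
  stopifnot(l_raw >= 1, s_snps >= 1)
  if (n_tag_groups <= 0) stop("domain error: tag-group count must be positive")
  if (n_tag_groups > s_snps) stop("tag groups cannot exceed SNP count")
  as.integer(round(l_raw * s_snps / n_tag_groups))
}

#' Calibrate the minimum ROH length for a cohort
#'
#' End-to-end calibration: control mean heterozygosity, smallest run
#' length with expected chance-run count below `alpha`, tag-group count
#' from LD pruning, and the LD-adjusted minimum segment length to feed
#' into [roh_params()] as `min_segment_snps`.
#'
#' @param panel a QC'd [genotype_panel].
#' @param alpha tolerated expected chance-run count (default 0.05).
#' @param r2_threshold,window_snps,step_snps pruning parameters, see
#'   [count_tag_groups()].
#' @param het_phenotype samples used for the heterozygosity estimate
#'   (default `"control"`, matching the calibration on controls).
#' @return A `calibration_result` list: `mean_het`, `n_snps`,
#'   `n_samples`, `alpha`, `raw_min_length`, `n_tag_groups`,
#'   `tag_fraction`, `adjusted_min_length`.
#' @export
calibrate_min_length <- function(panel, alpha = 0.05, r2_threshold = 0.5,
                                 window_snps = 50, step_snps = 5,
                                 het_phenotype = "control") {
  h <- realized_heterozygosity(panel, phenotype = het_phenotype)
  s <- n_variants(panel)
  n <- n_samples(panel)
  l_raw <- min_run_length(h, s, n, alpha)
  t_groups <- count_tag_groups(panel, r2_threshold, window_snps, step_snps)
  structure(
    list(mean_het = h, n_snps = s, n_samples = n, alpha = alpha,
         raw_min_length = l_raw, n_tag_groups = t_groups,
         tag_fraction = t_groups / s,
         adjusted_min_length = ld_adjusted_length(l_raw, s, t_groups)),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("calibration_result\n")
  cat(sprintf("  mean heterozygosity: %.4f (%d samples, %d SNPs)\n",
              x$mean_het, x$n_samples, x$n_snps))
  cat(sprintf("  raw minimum run length (alpha=%g): %d\n",
              x$alpha, x$raw_min_length))
  cat(sprintf("  tag groups: %d of %d SNPs (%.1f%% information reduction)\n",
              x$n_tag_groups, x$n_snps, 100 * (1 - x$tag_fraction)))
  cat(sprintf("  LD-adjusted minimum segment SNPs: %d\n",
              x$adjusted_min_length))
  invisible(x)
}

#' Write a calibration result as a key-value text block
#'
#' @param result a `calibration_result` from [calibrate_min_length()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_calibration <- function(result, path) {
  flat <- unclass(result)
  writeLines(paste(names(flat), vapply(flat, format, ""), sep = "\t"), path)
  invisible(path)
}
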