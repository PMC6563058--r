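# Broad-sense runs of homozygosity via a heterozygote-tolerant sliding
# window. A window of consecutive SNPs is scored homozygous when it holds
# at most a small number of heterozygous calls (2% of the window by
# default) and a bounded number of missing calls; a SNP is "in ROH" when
# a sufficient fraction of the windows covering it are homozygous, so a
# segment may contain isolated heterozygotes (genotyping error,
# mutation) without being split. Maximal runs of in-ROH SNPs, split at
# large inter-SNP gaps and trimmed to homozygous non-missing endpoints,
# become segments if they satisfy minimum SNP-count, span and density
# thresholds.

#' Parameters for the sliding-window ROH caller
#'
#' @param min_segment_snps minimum SNPs per reported segment. This is the
#'   cohort-calibrated "homozyg-SNP" value (73 for the study's discovery
#'   cohort, 100 for its replication cohort); see [calibrate_min_length()].
#' @param window_snps sliding-window length in SNPs (default 50).
#' @param window_het_max maximum heterozygous calls tolerated per window;
#'   default `ceiling(0.02 * window_snps)` so the 2%-heterozygote
#'   tolerance survives window resizing.
#' @param window_missing_max maximum missing calls per window (default 5).
#' @param snp_hit_threshold minimum fraction of covering windows that must
#'   be homozygous for a SNP to be in ROH (default 0.05).
#' @param min_segment_kb minimum segment span in kb (default 1000).
#' @param max_gap_kb runs are split where adjacent SNPs are further apart
#'   than this (default 1000).
#' @param min_density_kb_per_snp maximum span/SNP-count ratio in kb per
#'   SNP (default 50).
#' @return A validated `roh_params` list.
#' @export
roh_params <- function(min_segment_snps = 73,
                       window_snps = 50,
                       window_het_max = ceiling(0.02 * window_snps),
                       window_missing_max = 5,
                       snp_hit_threshold = 0.05,
                       min_segment_kb = 1000,
                       max_gap_kb = 1000,
                       min_density_kb_per_snp = 50) {
  p <- list(min_segment_snps = as.integer(min_segment_snps),
            window_snps = as.integer(window_snps),
            window_het_max = as.integer(window_het_max),
            window_missing_max = as.integer(window_missing_max),
            snp_hit_threshold = snp_hit_threshold,
            min_segment_kb = min_segment_kb,
            max_gap_kb = max_gap_kb,
            min_density_kb_per_snp = min_density_kb_per_snp)
  stopifnot(p$window_snps >= 1, p$min_segment_snps >= 1,
            p$window_snps <= p$min_segment_snps,
            p$window_het_max >= 0, p$window_missing_max >= 0,
            p$snp_hit_threshold > 0, p$snp_hit_threshold <= 1,
            p$min_segment_kb >= 0, p$max_gap_kb > 0,
            p$min_density_kb_per_snp > 0)
  structure(p, class = "roh_params")
}

#' Call runs of homozygosity in every sample of a panel
#'
#' Applies the sliding-window scan chromosome by chromosome and sample by
#' sample. Windows are fully contained in a chromosome; SNPs near
#' chromosome ends are covered by fewer windows, which the hit-fraction
#' denominator accounts for. Chromosomes shorter than the window yield no
#' calls. Output is deterministic and sorted by sample (panel order),
#' chromosome and start position.
#'
#' @param panel a QC'd [genotype_panel].
#' @param params a [roh_params()].
#' @return data.frame of segments: `sample_id`, `phenotype`, `chrom`,
#'   `start_bp`, `end_bp`, `start_snp`, `end_snp` (1-based, half-open
#'   global variant-column indices), `n_snps`, `length_kb`, `n_het`,
#'   `n_missing`.
#' @export
call_roh <- function(panel, params = roh_params()) {
  stopifnot(inherits(params, "roh_params"))
  blocks <- chrom_blocks(panel)
  g <- panel$genotypes
  out <- list()
  for (bi in seq_len(nrow(blocks))) {
    cols <- blocks$start[bi]:blocks$end[bi]
    if (length(cols) < params$window_snps) next
    pos <- panel$variants$pos_bp[cols]
    gap_break <- diff(pos) > params$max_gap_kb * 1000
    for (si in seq_len(nrow(g))) {
      segs <- scan_sample_chrom(g[si, cols], pos, gap_break, params)
      if (is.null(segs)) next
      segs$sample_id <- panel$samples$id[si]
      segs$phenotype <- panel$samples$phenotype[si]
      segs$chrom <- blocks$chrom[bi]
      segs$start_snp <- segs$start_snp + blocks$start[bi] - 1L
      segs$end_snp <- segs$end_snp + blocks$start[bi] - 1L
      out[[length(out) + 1L]] <- segs
    }
  }
  if (!length(out)) return(empty_segments())
  res <- do.call(rbind, out)
  ord <- order(match(res$sample_id, panel$samples$id), res$chrom,
               res$start_bp)
  res <- res[ord, c("sample_id", "phenotype", "chrom", "start_bp", "end_bp",
                    "start_snp", "end_snp", "n_snps", "length_kb", "n_het",
                    "n_missing")]
  rownames(res) <- NULL
  res
}

empty_segments <- function() {
  data.frame(sample_id = character(), phenotype = character(),
             chrom = integer(), start_bp = integer(), end_bp = integer(),
             start_snp = integer(), end_snp = integer(), n_snps = integer(),
             length_kb = numeric(), n_het = integer(), n_missing = integer(),
             stringsAsFactors = FALSE)
}

# one sample on one chromosome; indices local 1-based, half-open end
scan_sample_chrom <- function(geno, pos, gap_break, params) {
  s <- length(geno)
  w <- params$window_snps
  het <- !is.na(geno) & geno == 1L
  miss <- is.na(geno)

  # window scores: window j covers SNPs j .. j+w-1
  n_win <- s - w + 1L
  cs_het <- c(0L, cumsum(het))
  cs_miss <- c(0L, cumsum(miss))
  j <- seq_len(n_win)
  hom_win <- (cs_het[j + w] - cs_het[j]) <= params$window_het_max &
    (cs_miss[j + w] - cs_miss[j]) <= params$window_missing_max

  # per-SNP hit fraction over the windows that cover it
  i <- seq_len(s)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(i, n_win)
  cs_hw <- c(0L, cumsum(hom_win))
  hits <- cs_hw[hi + 1L] - cs_hw[lo]
  covering <- hi - lo + 1L
  # broad-sense: interior hets are tolerated (absorbed by the window
  # scores); ends are trimmed to homozygous non-missing calls below
  in_roh <- hits / covering >= params$snp_hit_threshold

  if (!any(in_roh)) return(NULL)

  # maximal runs of in-ROH SNPs, split at large gaps
  boundary <- c(TRUE, !in_roh[-s] | gap_break)      # run starts here
  run_id <- cumsum(boundary)
  run_id[!in_roh] <- 0L
  keep <- in_roh
  ids <- unique(run_id[keep])
  segs <- lapply(ids, function(id) {
    idx <- which(run_id == id)
    a <- idx[1]
    b <- idx[length(idx)]
    # trim so both endpoints are homozygous non-missing calls
    while (a <= b && (miss[a] || het[a])) a <- a + 1L
    while (b >= a && (miss[b] || het[b])) b <- b - 1L
    if (a > b) return(NULL)
    n <- b - a + 1L
    span_kb <- (pos[b] - pos[a]) / 1000
    if (n < params$min_segment_snps) return(NULL)
    if (span_kb < params$min_segment_kb) return(NULL)
    if (span_kb / n > params$min_density_kb_per_snp) return(NULL)
    data.frame(start_bp = pos[a], end_bp = pos[b],
               start_snp = a, end_snp = b + 1L, n_snps = n,
               length_kb = span_kb,
               n_het = sum(het[a:b]),
               n_missing = sum(miss[a:b]))
  })
  segs <- segs[!vapply(segs, is.null, TRUE)]
  if (!length(segs)) return(NULL)
  do.call(rbind, segs)
}

#' Count strict homozygous run starts
#'
#' Counts, over all samples and chromosomes, the (sample, start-position)
#' pairs that begin at least `run_length` consecutive homozygous calls
#' with no heterozygous and no missing call. Overlapping starts all
#' count. This is the null quantity behind the minimum-length
#' calibration: for independent SNPs with heterozygosity `h` the expected
#' count is `(S - L + 1) * N * (1 - h)^L` per chromosome.
#'
#' @param panel a [genotype_panel].
#' @param run_length minimum run length `L >= 1`.
#' @return Integer count.
#' @export
strict_run_scan <- function(panel, run_length) {
  stopifnot(run_length >= 1)
  blocks <- chrom_blocks(panel)
  g <- panel$genotypes
  total <- 0
  for (bi in seq_len(nrow(blocks))) {
    cols <- blocks$start[bi]:blocks$end[bi]
    s <- length(cols)
    if (s < run_length) next
    hom <- !is.na(g[, cols, drop = FALSE]) & g[, cols, drop = FALSE] != 1L
    cs <- cbind(0L, t(apply(hom, 1L, cumsum)))
    j <- seq_len(s - run_length + 1L)
    total <- total + sum(cs[, j + run_length, drop = FALSE] -
                           cs[, j, drop = FALSE] == run_length)
  }
  total
}

#' Per-sample ROH burden summary
#'
#' One row per panel sample with its segment count and summed segment
#' length, zero-filled for samples without any ROH -- the per-individual
#' table the global burden comparison runs on.
#'
#' @param segments segment table from [call_roh()].
#' @param panel the [genotype_panel] the segments were called on.
#' @return data.frame with `sample_id`, `phenotype`, `n_roh`,
#'   `total_length_bp`.
#' @export
per_sample_summary <- function(segments, panel) {
  ids <- panel$samples$id
  n_roh <- integer(length(ids))
  total <- numeric(length(ids))
  if (nrow(segments)) {
    agg_n <- tapply(segments$start_bp, segments$sample_id, length)
    agg_len <- tapply(segments$end_bp - segments$start_bp,
                      segments$sample_id, sum)
    m <- match(ids, names(agg_n))
    n_roh <- ifelse(is.na(m), 0L, as.integer(agg_n[m]))
    total <- ifelse(is.na(m), 0, as.numeric(agg_len[m]))
  }
  data.frame(sample_id = ids, phenotype = panel$samples$phenotype,
             n_roh = n_roh, total_length_bp = total,
             stringsAsFactors = FALSE)
}
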