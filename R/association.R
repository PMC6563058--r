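# Case-control association of ROH: global burden comparisons (t-tests on
# per-sample ROH count and total length), per-region chi-square carrier
# tests with odds ratios, candidate selection, cross-cohort pairing by
# coordinate overlap, fixed-effects inverse-variance meta-analysis, and
# cumulative length-distribution curves.

#' Global ROH burden comparison between cases and controls
#'
#' Two-sided t-tests (Welch by default; `pooled_variance = TRUE` for the
#' classical equal-variance form) comparing cases against controls on
#' the per-sample number of ROH and on the per-sample total ROH length.
#'
#' @param summary per-sample table from [per_sample_summary()].
#' @param pooled_variance use the pooled-variance t-test instead of
#'   Welch.
#' @return data.frame with one row per metric (`n_roh`,
#'   `total_length_bp`): group means and SDs, `t`, `df`, `p`.
#' @export
burden_tests <- function(summary, pooled_variance = FALSE) {
  is_case <- summary$phenotype == "case"
  if (sum(is_case) < 2 || sum(!is_case) < 2) {
    stop("test undefined: need at least two samples per group")
  }
  one <- function(metric) {
    x <- summary[[metric]][is_case]
    y <- summary[[metric]][!is_case]
    if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
      tt <- list(statistic = c(t = 0), parameter = c(df = NA_real_),
                 p.value = 1)
    } else {
      tt <- stats::t.test(x, y, var.equal = pooled_variance)
    }
    data.frame(metric = metric,
               mean_cases = mean(x), sd_cases = stats::sd(x),
               mean_controls = mean(y), sd_controls = stats::sd(y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  }
  rbind(one("n_roh"), one("total_length_bp"))
}

#' Chi-square test and odds ratio for a 2x2 carrier table
#'
#' Pearson chi-square with 1 degree of freedom, without continuity
#' correction by default (`yates = TRUE` applies it). The odds ratio is
#' `ad / bc`, computed on cells with 0.5 added to all four
#' (Haldane-Anscombe) if and only if any cell is zero.
#'
#' @param a,b case carriers, case non-carriers.
#' @param c_,d control carriers, control non-carriers.
#' @param yates apply the continuity correction.
#' @return `list(chi2, p, odds_ratio)`.
#' @export
chi2_region_test <- function(a, b, c_, d, yates = FALSE) {
  if (any(c(a, b, c_, d) < 0)) stop("domain error: negative counts")
  if (a + b == 0 || c_ + d == 0 || a + c_ == 0 || b + d == 0) {
    stop("domain error: 2x2 margins must be positive")
  }
  tab <- matrix(c(a, b, c_, d), 2, 2, byrow = TRUE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  cells <- if (any(tab == 0)) tab + 0.5 else tab
  or <- (cells[1, 1] * cells[2, 2]) / (cells[1, 2] * cells[2, 1])
  list(chi2 = unname(ct$statistic), p = ct$p.value, odds_ratio = or)
}

#' Per-region case-control association tests
#'
#' Builds the 2x2 carrier table of every consensus region (case
#' carriers / non-carriers vs control carriers / non-carriers) and
#' applies [chi2_region_test()].
#'
#' @param regions region table from [consensus_regions()].
#' @param samples sample table (`id`, `phenotype`).
#' @param yates apply the continuity correction.
#' @return data.frame: `region_id`, `chrom`, `start_bp`, `end_bp`,
#'   `n_case_carriers`, `n_case_noncarriers`, `n_control_carriers`,
#'   `n_control_noncarriers`, `odds_ratio`, `chi2`, `p`.
#' @export
region_association <- function(regions, samples, yates = FALSE) {
  n_cases <- sum(samples$phenotype == "case")
  n_controls <- sum(samples$phenotype == "control")
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    ids <- regions$carriers[[i]]
    ph <- samples$phenotype[match(ids, samples$id)]
    if (anyNA(ph)) stop("consistency error: carrier without phenotype")
    a <- sum(ph == "case")
    c_ <- sum(ph == "control")
    tst <- chi2_region_test(a, n_cases - a, c_, n_controls - c_, yates)
    data.frame(region_id = regions$region_id[i], chrom = regions$chrom[i],
               start_bp = regions$start_bp[i], end_bp = regions$end_bp[i],
               n_case_carriers = a, n_case_noncarriers = n_cases - a,
               n_control_carriers = c_,
               n_control_noncarriers = n_controls - c_,
               odds_ratio = tst$odds_ratio, chi2 = tst$chi2, p = tst$p,
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(region_id = character(), chrom = integer(),
                      start_bp = integer(), end_bp = integer(),
                      n_case_carriers = integer(),
                      n_case_noncarriers = integer(),
                      n_control_carriers = integer(),
                      n_control_noncarriers = integer(),
                      odds_ratio = numeric(), chi2 = numeric(),
                      p = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Select candidate regions by p-value
#'
#' Regions with `p` strictly below `p_max` (the study carried discovery
#' regions with p < 0.01 into replication), sorted by increasing p.
#'
#' @param region_results table from [region_association()].
#' @param p_max selection threshold (default 0.01).
#' @return Subset of `region_results`.
#' @export
select_candidates <- function(region_results, p_max = 0.01) {
  out <- region_results[region_results$p < p_max, , drop = FALSE]
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pair discovery and replication regions by coordinate overlap
#'
#' Matches regions whose base-pair intervals intersect on the same
#' chromosome and reports the intersection span (the cross-cohort
#' consensus region). Regions of one list may pair with several of the
#' other.
#'
#' @param discovery_regions,replication_regions tables with `region_id`,
#'   `chrom`, `start_bp`, `end_bp` (both on the same genome build).
#' @return data.frame: `chrom`, `discovery_id`, `replication_id`, the
#'   two source spans, and `overlap_start_bp` / `overlap_end_bp`.
#' @export
merge_overlap <- function(discovery_regions, replication_regions) {
  empty <- data.frame(chrom = integer(), discovery_id = character(),
                      replication_id = character(),
                      discovery_start_bp = integer(),
                      discovery_end_bp = integer(),
                      replication_start_bp = integer(),
                      replication_end_bp = integer(),
                      overlap_start_bp = integer(),
                      overlap_end_bp = integer(), stringsAsFactors = FALSE)
  if (!nrow(discovery_regions) || !nrow(replication_regions)) return(empty)
  dr <- IRanges::IRanges(start = discovery_regions$start_bp,
                         end = discovery_regions$end_bp)
  rr <- IRanges::IRanges(start = replication_regions$start_bp,
                         end = replication_regions$end_bp)
  hits <- IRanges::findOverlaps(dr, rr)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  same_chrom <- discovery_regions$chrom[qi] == replication_regions$chrom[si]
  qi <- qi[same_chrom]
  si <- si[same_chrom]
  if (!length(qi)) return(empty)
  inter <- IRanges::pintersect(dr[qi], rr[si])
  data.frame(
    chrom = discovery_regions$chrom[qi],
    discovery_id = discovery_regions$region_id[qi],
    replication_id = replication_regions$region_id[si],
    discovery_start_bp = discovery_regions$start_bp[qi],
    discovery_end_bp = discovery_regions$end_bp[qi],
    replication_start_bp = replication_regions$start_bp[si],
    replication_end_bp = replication_regions$end_bp[si],
    overlap_start_bp = IRanges::start(inter),
    overlap_end_bp = IRanges::end(inter),
    stringsAsFactors = FALSE
  )
}

#' Fixed-effects inverse-variance meta-analysis of 2x2 tables
#'
#' Per study: log odds ratio with standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)` (on Haldane-corrected cells if any cell
#' is zero). Studies are weighted by inverse variance
#' `w = 1 / SE^2`; the pooled log OR is the weighted mean, its SE is
#' `1 / sqrt(sum(w))`, and the two-sided p comes from the normal
#' approximation of `z = pooled / SE`.
#'
#' @param effect_tables list of 2x2 tables, each
#'   `c(a, b, c, d)` = (case carriers, case non-carriers, control
#'   carriers, control non-carriers) or a 2x2 matrix in that row order.
#' @return `list(studies, pooled_log_or, pooled_se, z, p)`; `studies` is
#'   a data.frame of per-study `log_or`, `se`, `weight`.
#' @export
meta_fixed <- function(effect_tables) {
  stopifnot(length(effect_tables) >= 1)
  rows <- lapply(seq_along(effect_tables), function(i) {
    tb <- effect_tables[[i]]
    cells <- as.numeric(t(tb))[1:4]
    if (any(cells < 0)) stop("domain error: negative counts")
    a <- cells[1]; b <- cells[2]; c_ <- cells[3]; d <- cells[4]
    if (a + b == 0 || c_ + d == 0 || a + c_ == 0 || b + d == 0) {
      warning("study ", i, " has an empty margin; excluded from pooling")
      return(NULL)
    }
    if (any(cells == 0)) {
      a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
    }
    log_or <- log(a * d / (b * c_))
    se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
    data.frame(study = i, log_or = log_or, se = se, weight = 1 / se^2)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) stop("no study with usable margins")
  studies <- do.call(rbind, rows)
  w <- studies$weight
  pooled <- sum(w * studies$log_or) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- pooled / se
  list(studies = studies, pooled_log_or = pooled, pooled_se = se, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Cumulative ROH length distribution per phenotype group
#'
#' For every observed segment length `x` (and 0), the fraction of the
#' group's samples possessing at least one ROH of length `>= x` -- the
#' survival-type curve used to compare the global length distribution of
#' cases and controls.
#'
#' @param segments segment table from [call_roh()].
#' @param panel the [genotype_panel] (supplies the group denominators).
#' @return data.frame: `phenotype`, `length_bp`, `fraction`; fractions
#'   are non-increasing in length within a group.
#' @export
cumulative_curve <- function(segments, panel) {
  grid <- sort(unique(segments$end_bp - segments$start_bp))
  out <- lapply(c("case", "control"), function(ph) {
    ids <- panel$samples$id[panel$samples$phenotype == ph]
    if (!length(ids) || !length(grid)) return(NULL)
    seg_ph <- segments[segments$sample_id %in% ids, , drop = FALSE]
    max_len <- rep(0, length(ids))    # samples without ROH stay at 0
    if (nrow(seg_ph)) {
      mx <- tapply(seg_ph$end_bp - seg_ph$start_bp, seg_ph$sample_id, max)
      m <- match(ids, names(mx))
      max_len[!is.na(m)] <- mx[m[!is.na(m)]]
    }
    data.frame(phenotype = ph, length_bp = grid,
               fraction = vapply(grid, function(x) mean(max_len >= x), 1),
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    return(data.frame(phenotype = character(), length_bp = numeric(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
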