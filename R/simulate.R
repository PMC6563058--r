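# Synthetic case-control genotype cohorts.
#
# Genomes are built from per-SNP allele frequencies and block LD: within
# each block of consecutive SNPs a finite pool of haplotypes is drawn from
# the frequencies, and every individual copies two pool haplotypes (with
# replacement). Finite pools create realistic LD and occasional chance
# autozygosity; haplotypes_per_block = Inf degenerates to independent
# Hardy-Weinberg draws. Planted autozygous tracts duplicate one haplotype
# onto the other over the tract span, so allele frequencies inside the
# tract stay realistic (identity-by-descent, not forced reference
# homozygosity). Heterozygote-miscall error and missingness are applied
# last, in that order.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the statistical structure the homozygosity analysis
#' assumes: a biallelic autosomal SNP array with block LD and mean
#' heterozygosity about 0.35 in controls.
#'
#' @param n_cases,n_controls sample counts.
#' @param n_snps total SNP count, split evenly over `n_chromosomes`.
#' @param n_chromosomes number of autosomes simulated.
#' @param allele_freq_law `list(law="uniform", lo=, hi=)` or
#'   `list(law="beta", a=, b=)` for the per-SNP allele-B frequency.
#' @param ld_block_size_snps SNPs per LD block (1 = independent SNPs).
#' @param haplotypes_per_block pool size per block; `Inf` for direct
#'   Hardy-Weinberg sampling without a finite pool.
#' @param target_mean_heterozygosity if non-`NULL`, drawn frequencies are
#'   rescaled by a single factor so the analytic mean heterozygosity
#'   (including the finite-pool shrinkage `1 - 1/K`) equals this target.
#'   `NULL` uses the frequency law as drawn.
#' @param planted_regions list of lists with fields `chromosome`,
#'   `start_snp_index` (1-based within the chromosome), `length_snps`,
#'   `case_carrier_fraction`, `control_carrier_fraction`. Regions on one
#'   chromosome must not overlap.
#' @param het_error_rate probability a truly homozygous call is rendered
#'   heterozygous (genotyping error / artificial heterozygosity).
#' @param missing_rate probability any call is set missing.
#' @param snp_spacing_bp fixed inter-SNP spacing in bp; 15 kb by default so
#'   a 73-SNP run spans just over 1 Mb, as on a genome-wide array of this
#'   density.
#' @param seed integer seed; every stage (frequencies, haplotype pools,
#'   copying, carriers, errors, missingness) uses a sub-stream derived
#'   from it, so the run is fully reproducible and stages are stable when
#'   unrelated knobs change.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_cases = 100,
                              n_controls = 100,
                              n_snps = 5000,
                              n_chromosomes = 2,
                              allele_freq_law = list(law = "uniform",
                                                     lo = 0.05, hi = 0.5),
                              ld_block_size_snps = 25,
                              haplotypes_per_block = 20,
                              target_mean_heterozygosity = 0.35,
                              planted_regions = list(),
                              het_error_rate = 0,
                              missing_rate = 0,
                              snp_spacing_bp = 15000,
                              seed = 1) {
  cfg <- list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_snps = as.integer(n_snps), n_chromosomes = as.integer(n_chromosomes),
    allele_freq_law = allele_freq_law,
    ld_block_size_snps = as.integer(ld_block_size_snps),
    haplotypes_per_block = haplotypes_per_block,
    target_mean_heterozygosity = target_mean_heterozygosity,
    planted_regions = planted_regions,
    het_error_rate = het_error_rate, missing_rate = missing_rate,
    snp_spacing_bp = as.integer(snp_spacing_bp),
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(n_cases > 0, n_controls > 0, n_snps > 0, n_chromosomes > 0,
              ld_block_size_snps >= 1,
              het_error_rate >= 0, het_error_rate < 1,
              missing_rate >= 0, missing_rate < 1,
              is.infinite(haplotypes_per_block) || haplotypes_per_block >= 2)
    if (!is.null(target_mean_heterozygosity)) {
      stopifnot(target_mean_heterozygosity > 0,
                target_mean_heterozygosity < 1)
    }
  })
  snps_per_chrom <- chrom_sizes(cfg)
  seen <- list()
  for (r in cfg$planted_regions) {
    stopifnot(all(c("chromosome", "start_snp_index", "length_snps",
                    "case_carrier_fraction", "control_carrier_fraction")
                  %in% names(r)))
    if (r$start_snp_index < 1 ||
        r$start_snp_index + r$length_snps - 1 > snps_per_chrom[r$chromosome]) {
      stop("config error: planted region outside chromosome ", r$chromosome)
    }
    stopifnot(r$case_carrier_fraction >= 0, r$case_carrier_fraction <= 1,
              r$control_carrier_fraction >= 0, r$control_carrier_fraction <= 1)
    key <- as.character(r$chromosome)
    for (prev in seen[[key]]) {
      if (r$start_snp_index <= prev[2] &&
          r$start_snp_index + r$length_snps - 1 >= prev[1]) {
        stop("config error: planted regions overlap on chromosome ",
             r$chromosome)
      }
    }
    seen[[key]] <- c(seen[[key]],
                     list(c(r$start_snp_index,
                            r$start_snp_index + r$length_snps - 1)))
  }
  structure(cfg, class = "simulation_config")
}

# SNPs per chromosome: as even a split as possible
chrom_sizes <- function(config) {
  base <- config$n_snps %/% config$n_chromosomes
  extra <- config$n_snps %% config$n_chromosomes
  sizes <- rep(base, config$n_chromosomes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

# deterministic per-stage sub-seed, kept inside 32-bit integer range
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stage * 69621) %% 2147483647)
}

draw_freqs <- function(law, n) {
  switch(law$law,
    uniform = stats::runif(n, law$lo, law$hi),
    beta = stats::rbeta(n, law$a, law$b),
    stop("unknown allele frequency law: ", law$law)
  )
}

#' Analytic mean heterozygosity of a simulation configuration
#'
#' Closed-form expectation of the heterozygous-call fraction before
#' genotyping error and missingness: `E[2p(1-p)]` under the frequency law,
#' shrunk by `1 - 1/K` for a finite haplotype pool of size `K` (two pool
#' draws coincide in frequency within a block). If the configuration sets
#' `target_mean_heterozygosity`, that target is returned, since the
#' generator rescales frequencies to meet it.
#'
#' @param config a [simulation_config()].
#' @return Expected fraction of heterozygous calls.
#' @export
expected_mean_heterozygosity <- function(config) {
  if (!is.null(config$target_mean_heterozygosity)) {
    return(config$target_mean_heterozygosity)
  }
  law <- config$allele_freq_law
  m <- switch(law$law,
    uniform = {
      ep <- (law$lo + law$hi) / 2
      ep2 <- (law$lo^2 + law$lo * law$hi + law$hi^2) / 3
      2 * (ep - ep2)
    },
    beta = {
      ab <- law$a + law$b
      2 * (law$a / ab - law$a * (law$a + 1) / (ab * (ab + 1)))
    },
    stop("unknown allele frequency law: ", law$law)
  )
  k <- config$haplotypes_per_block
  if (is.finite(k)) m <- m * (1 - 1 / k)
  m
}

# rescale frequencies p -> c*p (clipped to [1e-4, 0.5]) so the analytic
# mean het over the drawn vector hits the target
rescale_freqs_to_target <- function(p, target, pool_k) {
  shrink <- if (is.finite(pool_k)) 1 - 1 / pool_k else 1
  mean_het <- function(cc) {
    q <- pmin(pmax(cc * p, 1e-4), 0.5)
    mean(2 * q * (1 - q)) * shrink
  }
  if (mean_het(10) < target) {
    stop("target_mean_heterozygosity unattainable for this frequency law")
  }
  cc <- stats::uniroot(function(x) mean_het(x) - target,
                       lower = 1e-3, upper = 10, tol = 1e-10)$root
  pmin(pmax(cc * p, 1e-4), 0.5)
}

#' Simulate a case-control genotype panel with known truth
#'
#' Generates a [genotype_panel] under the copying model described in
#' [simulation_config()] together with a truth table recording, for every
#' planted autozygous tract, its exact SNP-index span and the identities
#' of the samples that carry it. Haplotype duplication for carriers is
#' applied before error and missingness, so with zero error rates every
#' carrier is perfectly homozygous and complete over the tract.
#'
#' @param config a [simulation_config()].
#' @return `list(panel = genotype_panel, truth = data.frame)`; the truth
#'   table has one row per planted region (`region_id`, `chrom`,
#'   `start_snp`, `end_snp` half-open global indices, `start_bp`,
#'   `end_bp`, `n_case_carriers`, `n_control_carriers`) and a list-column
#'   `carriers` of sample identifiers.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_cases + config$n_controls
  s <- config$n_snps
  sizes <- chrom_sizes(config)
  chrom <- rep(seq_len(config$n_chromosomes), sizes)
  pos_in_chrom <- unlist(lapply(sizes, seq_len), use.names = FALSE)
  pos_bp <- pos_in_chrom * config$snp_spacing_bp
  chrom_offset <- c(0L, cumsum(sizes))   # global index offset per chromosome

  set.seed(stage_seed(config$seed, 1L))
  p <- draw_freqs(config$allele_freq_law, s)
  if (!is.null(config$target_mean_heterozygosity)) {
    p <- rescale_freqs_to_target(p, config$target_mean_heterozygosity,
                                 config$haplotypes_per_block)
  }

  k <- config$haplotypes_per_block
  h1 <- matrix(0L, n, s)
  h2 <- matrix(0L, n, s)
  set.seed(stage_seed(config$seed, 2L))
  for (cc in seq_len(config$n_chromosomes)) {
    cols <- (chrom_offset[cc] + 1L):chrom_offset[cc + 1L]
    starts <- seq(1L, length(cols), by = config$ld_block_size_snps)
    for (b in starts) {
      blk <- cols[b:min(b + config$ld_block_size_snps - 1L, length(cols))]
      w <- length(blk)
      if (is.finite(k)) {
        pool <- matrix(stats::rbinom(k * w, 1L, rep(p[blk], each = k)), k, w)
        i1 <- sample.int(k, n, replace = TRUE)
        i2 <- sample.int(k, n, replace = TRUE)
        h1[, blk] <- pool[i1, , drop = FALSE]
        h2[, blk] <- pool[i2, , drop = FALSE]
      } else {
        h1[, blk] <- matrix(stats::rbinom(n * w, 1L, rep(p[blk], each = n)),
                            n, w)
        h2[, blk] <- matrix(stats::rbinom(n * w, 1L, rep(p[blk], each = n)),
                            n, w)
      }
    }
  }

  ids <- c(sprintf("case_%04d", seq_len(config$n_cases)),
           sprintf("ctrl_%04d", seq_len(config$n_controls)))
  phenotype <- rep(c("case", "control"),
                   c(config$n_cases, config$n_controls))

  set.seed(stage_seed(config$seed, 3L))
  truth <- vector("list", length(config$planted_regions))
  for (ri in seq_along(config$planted_regions)) {
    r <- config$planted_regions[[ri]]
    g0 <- chrom_offset[r$chromosome] + r$start_snp_index
    span <- g0:(g0 + r$length_snps - 1L)
    is_case <- phenotype == "case"
    carrier <- logical(n)
    carrier[is_case] <- stats::runif(sum(is_case)) < r$case_carrier_fraction
    carrier[!is_case] <- stats::runif(sum(!is_case)) < r$control_carrier_fraction
    h2[carrier, span] <- h1[carrier, span]
    truth[[ri]] <- data.frame(
      region_id = sprintf("planted_%02d", ri),
      chrom = r$chromosome,
      start_snp = g0, end_snp = g0 + r$length_snps,  # half-open, global
      start_bp = pos_bp[g0], end_bp = pos_bp[g0 + r$length_snps - 1L],
      n_case_carriers = sum(carrier & is_case),
      n_control_carriers = sum(carrier & !is_case),
      stringsAsFactors = FALSE
    )
    truth[[ri]]$carriers <- list(ids[carrier])
  }
  truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
    region_id = character(), chrom = integer(), start_snp = integer(),
    end_snp = integer(), start_bp = integer(), end_bp = integer(),
    n_case_carriers = integer(), n_control_carriers = integer()
  )

  g <- h1 + h2

  if (config$het_error_rate > 0) {
    set.seed(stage_seed(config$seed, 4L))
    hom <- which(g != 1L)
    flip <- hom[stats::runif(length(hom)) < config$het_error_rate]
    g[flip] <- 1L
  }
  if (config$missing_rate > 0) {
    set.seed(stage_seed(config$seed, 5L))
    g[stats::runif(length(g)) < config$missing_rate] <- NA_integer_
  }

  variants <- data.frame(
    chrom = chrom,
    id = sprintf("snp_c%d_%05d", chrom, pos_in_chrom),
    pos_bp = pos_bp,
    allele_a = "A", allele_b = "B",
    stringsAsFactors = FALSE
  )
  panel <- genotype_panel(g, variants,
                          data.frame(id = ids, phenotype = phenotype,
                                     stringsAsFactors = FALSE))
  list(panel = panel, truth = truth)
}

#' Realized heterozygosity of a panel
#'
#' Fraction of non-missing genotype calls that are heterozygous, over all
#' samples or a phenotype subset. This is the quantity the minimum-length
#' calibration starts from (the study's controls showed 0.35).
#'
#' @param panel a [genotype_panel].
#' @param phenotype optional: `"case"` or `"control"` to restrict samples.
#' @return Fraction in `[0, 1]`.
#' @export
realized_heterozygosity <- function(panel, phenotype = NULL) {
  g <- panel$genotypes
  if (!is.null(phenotype)) {
    g <- g[panel$samples$phenotype == phenotype, , drop = FALSE]
  }
  n_called <- sum(!is.na(g))
  if (n_called == 0L) stop("undefined: all genotype calls are missing")
  sum(g == 1L, na.rm = TRUE) / n_called
}
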