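# In-code fixture builders shared across test files.

# minimal panel from a genotype matrix; evenly spaced SNPs
make_panel <- function(genotypes, chrom = NULL, pos_bp = NULL,
                       phenotype = NULL, spacing_bp = 15000L) {
  genotypes <- as.matrix(genotypes)
  n <- nrow(genotypes)
  s <- ncol(genotypes)
  if (is.null(chrom)) chrom <- rep(1L, s)
  if (is.null(pos_bp)) {
    pos_bp <- unlist(lapply(split(seq_len(s), chrom)[as.character(unique(chrom))],
                            function(ix) seq_along(ix) * spacing_bp),
                     use.names = FALSE)
  }
  if (is.null(phenotype)) {
    phenotype <- rep(c("case", "control"), length.out = n)
  }
  genotype_panel(
    genotypes,
    data.frame(chrom = chrom, id = sprintf("snp%04d", seq_len(s)),
               pos_bp = pos_bp, allele_a = "A", allele_b = "B",
               stringsAsFactors = FALSE),
    data.frame(id = sprintf("s%03d", seq_len(n)), phenotype = phenotype,
               stringsAsFactors = FALSE)
  )
}

# random panel with tunable het/missing rates (hom-rich so ROH arise)
random_panel <- function(seed, n = 20, s = 300, het_rate = 0.12,
                         miss_rate = 0.03, n_chrom = 2,
                         spacing_bp = 15000L, gappy = FALSE) {
  set.seed(seed)
  p_hom <- (1 - het_rate - miss_rate) / 2
  g <- matrix(
    sample(c(0L, 1L, 2L, NA_integer_), n * s, replace = TRUE,
           prob = c(p_hom, het_rate, p_hom, miss_rate)),
    n, s
  )
  chrom <- sort(rep_len(seq_len(n_chrom), s))
  pos <- unlist(lapply(split(seq_len(s), chrom), function(ix) {
    step <- if (gappy) {
      sample(c(spacing_bp, 2L * spacing_bp, 1500000L), length(ix),
             replace = TRUE, prob = c(0.8, 0.15, 0.05))
    } else {
      rep(spacing_bp, length(ix))
    }
    cumsum(step)
  }), use.names = FALSE)
  make_panel(g, chrom = chrom, pos_bp = pos)
}
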