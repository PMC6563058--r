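#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact conditional test for a biallelic genotype table.
#' Conditional on the observed allele counts, the number of heterozygotes
#' follows a known discrete distribution under random mating; the p-value
#' sums the probabilities of every attainable heterozygote count whose
#' conditional probability does not exceed that of the observed count.
#' This avoids the chi-square approximation's failure at small counts,
#' which matters for the stringent thresholds (p < 1e-5) used in marker
#' QC.
#'
#' @param n_hom_a,n_het,n_hom_b genotype counts (homozygous A,
#'   heterozygous, homozygous B); non-negative, not all zero.
#' @return Exact two-sided p-value in `(0, 1]`.
#' @export
hwe_exact_p <- function(n_hom_a, n_het, n_hom_b) {
  if (n_hom_a < 0 || n_het < 0 || n_hom_b < 0) {
    stop("domain error: genotype counts must be non-negative")
  }
  n <- n_hom_a + n_het + n_hom_b
  if (n == 0) stop("domain error: all genotype counts are zero")
  # rare-allele copy count; symmetric in allele labels
  r <- 2L * min(n_hom_a, n_hom_b) + n_het
  dist <- hwe_het_distribution(n, r)
  p_obs <- dist$prob[match(n_het, dist$het)]
  sum(dist$prob[dist$prob <= p_obs * (1 + 1e-9)])
}

# conditional distribution of the heterozygote count given n samples and
# r copies of the rarer allele: attainable counts share r's parity
hwe_het_distribution <- function(n, r) {
  het <- seq(r %% 2L, min(r, 2L * n - r), by = 2L)
  hom_rare <- (r - het) %/% 2L
  hom_common <- n - het - hom_rare
  logp <- lgamma(n + 1) - lgamma(hom_rare + 1) - lgamma(het + 1) -
    lgamma(hom_common + 1) + het * log(2)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  data.frame(het = het, prob = prob)
}
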