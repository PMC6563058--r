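#' Construct a genotype panel
#'
#' A `genotype_panel` bundles a samples-by-variants genotype matrix with its
#' variant map and sample (phenotype) table. It is the substrate every stage
#' of the homozygosity analysis consumes: QC, ROH calling, length
#' calibration, consensus-region construction and association testing.
#'
#' Genotypes are coded as allele-B dosage: `0` (homozygous A), `1`
#' (heterozygous), `2` (homozygous B), `NA` (missing). Allele polarity is
#' irrelevant downstream -- only homozygous / heterozygous / missing status
#' is ever used -- so readers preserve file polarity without re-orienting.
#'
#' @param genotypes integer matrix, samples in rows, variants in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param variants data.frame with columns `chrom` (autosome number 1-22),
#'   `id`, `pos_bp` (1-based), `allele_a`, `allele_b`. Within each
#'   chromosome positions must be strictly increasing, and each
#'   chromosome's variants must form one contiguous block.
#' @param samples data.frame with columns `id` (unique), `phenotype`
#'   (`"case"` or `"control"`) and optionally `cohort`.
#'
#' @return An object of class `genotype_panel` with elements `genotypes`,
#'   `variants`, `samples`.
#' @export
genotype_panel <- function(genotypes, variants, samples) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(samples$cohort)) samples$cohort <- NA_character_
  panel <- structure(
    list(genotypes = genotypes, variants = variants, samples = samples),
    class = "genotype_panel"
  )
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  g <- panel$genotypes
  v <- panel$variants
  s <- panel$samples
  need_v <- c("chrom", "id", "pos_bp", "allele_a", "allele_b")
  if (!all(need_v %in% names(v))) {
    stop("variant table must have columns: ", paste(need_v, collapse = ", "))
  }
  if (!all(c("id", "phenotype") %in% names(s))) {
    stop("sample table must have columns: id, phenotype")
  }
  if (nrow(g) != nrow(s)) {
    stop("genotype matrix has ", nrow(g), " rows but ", nrow(s), " samples")
  }
  if (ncol(g) != nrow(v)) {
    stop("genotype matrix has ", ncol(g), " columns but ", nrow(v),
         " variants")
  }
  bad <- !(g %in% c(0L, 1L, 2L)) & !is.na(g)
  if (any(bad)) stop("genotype entries must be 0, 1, 2 or NA")
  if (anyDuplicated(s$id)) stop("sample identifiers must be unique")
  if (!all(s$phenotype %in% c("case", "control"))) {
    stop("phenotype must be 'case' or 'control'")
  }
  if (any(v$pos_bp < 1)) stop("base-pair positions must be >= 1")
  chrom <- v$chrom
  if (any(rle(chrom)$values != unique(chrom))) {
    stop("variants of one chromosome must be contiguous in the map")
  }
  for (cc in unique(chrom)) {
    p <- v$pos_bp[chrom == cc]
    if (any(diff(p) <= 0)) {
      stop("positions on chromosome ", cc,
           " must be strictly increasing (duplicate or unsorted position)")
    }
  }
  invisible(panel)
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$samples), "samples x", nrow(x$variants),
      "variants on", length(unique(x$variants$chrom)), "chromosome(s)\n")
  tab <- table(x$samples$phenotype)
  cat("  phenotypes:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missingness: %.3f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$genotypes)

#' Subset a genotype panel
#'
#' @param x a `genotype_panel`.
#' @param i sample index (logical, integer or character ids).
#' @param j variant index (logical, integer or character ids).
#' @param ... unused.
#' @return The subsetted `genotype_panel`.
#' @export
`[.genotype_panel` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$samples))
  if (missing(j)) j <- seq_len(nrow(x$variants))
  if (is.character(i)) i <- match(i, x$samples$id)
  if (is.character(j)) j <- match(j, x$variants$id)
  genotype_panel(
    x$genotypes[i, j, drop = FALSE],
    x$variants[j, , drop = FALSE],
    x$samples[i, , drop = FALSE]
  )
}

#' Number of samples / variants in a panel
#' @param panel a `genotype_panel`.
#' @return Integer count.
#' @export
n_samples <- function(panel) nrow(panel$samples)

#' @rdname n_samples
#' @export
n_variants <- function(panel) nrow(panel$variants)

# start/end column index (half-open) of each chromosome block
chrom_blocks <- function(panel) {
  r <- rle(panel$variants$chrom)
  end <- cumsum(r$lengths)
  data.frame(chrom = r$values, start = end - r$lengths + 1L, end = end)
}
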