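# PLINK 1 binary triplet codec.
#
# .bed layout: 3 magic bytes (0x6c 0x1b, then 0x01 for SNP-major mode),
# followed, per variant, by ceiling(N/4) data bytes. Each byte packs four
# samples, two bits each, least-significant pair first:
#   00 = homozygous allele A, 01 = missing, 10 = heterozygous,
#   11 = homozygous allele B.
# Only SNP-major mode is accepted; the legacy individual-major mode (third
# byte 0x00) is rejected rather than silently transposed.

BED_MAGIC <- as.raw(c(0x6c, 0x1b))
BED_SNP_MAJOR <- as.raw(0x01)

# dosage value for each 2-bit code 00,01,10,11
.bed_code_to_geno <- c(0L, NA_integer_, 1L, 2L)
# 2-bit code for each dosage 0,1,2 (missing handled separately)
.geno_to_bed_code <- c(0L, 2L, 3L)

# 256 x 4 lookup: decoded genotype of the k-th packed sample in each byte
.bed_lookup <- local({
  bytes <- 0:255
  sapply(0:3, function(k) .bed_code_to_geno[bitwAnd(bitwShiftR(bytes, 2L * k), 3L) + 1L])
})

#' Read a PLINK .bed/.bim/.fam triplet
#'
#' Decodes a binary genotype triplet in SNP-major mode into a
#' [genotype_panel]. Phenotypes are taken from the sixth .fam column
#' (1 = control, 2 = case); panels without case/control assignment are
#' rejected because every downstream stage is a case-control comparison.
#'
#' @param bed_path,bim_path,fam_path paths to the three files. If
#'   `bim_path`/`fam_path` are omitted they are derived from `bed_path` by
#'   extension substitution.
#' @param cohort optional cohort label stored on every sample
#'   (e.g. `"discovery"` or `"replication"`).
#' @return A [genotype_panel].
#' @export
read_bed_triplet <- function(bed_path,
                             bim_path = sub("\\.bed$", ".bim", bed_path),
                             fam_path = sub("\\.bed$", ".fam", bed_path),
                             cohort = NA_character_) {
  for (p in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  bim <- utils::read.table(bim_path, header = FALSE, sep = "\t",
                           colClasses = c("integer", "character", "numeric",
                                          "integer", "character", "character"))
  names(bim) <- c("chrom", "id", "cm", "pos_bp", "allele_a", "allele_b")
  fam <- utils::read.table(fam_path, header = FALSE,
                           colClasses = c("character", "character",
                                          "character", "character",
                                          "character", "integer"))
  names(fam) <- c("fid", "iid", "pat", "mat", "sex", "pheno")
  if (!all(fam$pheno %in% c(1L, 2L))) {
    stop("phenotype unassigned: .fam phenotype column must be 1 (control) ",
         "or 2 (case) for every sample")
  }
  n <- nrow(fam)
  s <- nrow(bim)

  con <- file(bed_path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 3L)
  if (length(magic) < 3L || !identical(magic[1:2], BED_MAGIC)) {
    stop("format error: not a .bed file (magic bytes mismatch)")
  }
  if (magic[3] != BED_SNP_MAJOR) {
    stop("format error: .bed is in individual-major mode; ",
         "only SNP-major mode is supported")
  }
  bpv <- (n + 3L) %/% 4L
  body <- readBin(con, "raw", n = bpv * s + 1L)
  if (length(body) != bpv * s) {
    stop("truncation error: .bed body has ", length(body),
         " bytes, expected ", bpv * s, " for ", n, " samples x ", s,
         " variants")
  }
  bytes <- matrix(as.integer(body), nrow = bpv, ncol = s)
  dec <- matrix(NA_integer_, nrow = 4L * bpv, ncol = s)
  for (k in 1:4) {
    dec[seq(k, by = 4L, length.out = bpv), ] <-
      matrix(.bed_lookup[bytes + 1L, k], nrow = bpv, ncol = s)
  }
  genotypes <- dec[seq_len(n), , drop = FALSE]

  samples <- data.frame(
    id = fam$iid,
    phenotype = c("control", "case")[fam$pheno],
    cohort = cohort,
    stringsAsFactors = FALSE
  )
  variants <- bim[, c("chrom", "id", "pos_bp", "allele_a", "allele_b")]
  tryCatch(
    genotype_panel(genotypes, variants, samples),
    error = function(e) stop("map error: ", conditionMessage(e))
  )
}

#' Write a genotype panel as a PLINK .bed/.bim/.fam triplet
#'
#' Inverse of [read_bed_triplet()]: emits SNP-major .bed plus tab-separated
#' 6-column .bim and .fam. Output bytes are deterministic for a given
#' panel, and a write/read round trip reproduces the panel exactly.
#'
#' @param panel a [genotype_panel] with at least one sample and one variant.
#' @param out_prefix path prefix; `.bed`, `.bim` and `.fam` are appended.
#' @return Invisibly, the three file paths.
#' @export
write_bed_triplet <- function(panel, out_prefix) {
  validate_panel(panel)
  n <- n_samples(panel)
  s <- n_variants(panel)
  if (n == 0L || s == 0L) stop("empty panel: nothing to write")

  g <- panel$genotypes
  codes <- matrix(1L, nrow = n, ncol = s)            # 01 = missing
  ok <- !is.na(g)
  codes[ok] <- .geno_to_bed_code[g[ok] + 1L]
  bpv <- (n + 3L) %/% 4L
  pad <- 4L * bpv - n
  if (pad > 0L) codes <- rbind(codes, matrix(0L, nrow = pad, ncol = s))
  dim(codes) <- c(4L, bpv * s)
  bytes <- as.raw(codes[1, ] + 4L * codes[2, ] + 16L * codes[3, ] +
                    64L * codes[4, ])

  bed <- paste0(out_prefix, ".bed")
  bim <- paste0(out_prefix, ".bim")
  fam <- paste0(out_prefix, ".fam")
  con <- file(bed, "wb")
  writeBin(c(BED_MAGIC, BED_SNP_MAJOR), con)
  writeBin(bytes, con)
  close(con)

  v <- panel$variants
  utils::write.table(
    data.frame(v$chrom, v$id, 0, v$pos_bp, v$allele_a, v$allele_b),
    bim, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  sm <- panel$samples
  utils::write.table(
    data.frame(sm$id, sm$id, 0, 0, 0,
               ifelse(sm$phenotype == "case", 2L, 1L)),
    fam, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(c(bed = bed, bim = bim, fam = fam))
}
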