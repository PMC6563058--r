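# Plain-text genotype matrix dialect: a human-readable fixture format
# equivalent to the binary triplet.
#
# Tab-separated. Header: sample_id, phenotype, then one column per variant
# named "chrom:pos:id". Each following row: sample identifier, "case" or
# "control", then genotypes in {0, 1, 2, NA}. Bare variant names (no
# chrom:pos: prefix) are placed on chromosome 1 at consecutive positions.

#' Read a genotype panel from the plain-text matrix dialect
#'
#' @param path path to a tab-separated text matrix (see Details).
#' @param cohort optional cohort label stored on every sample.
#' @details The header row names the variants; `chrom:pos:id` tokens carry
#'   the map, bare tokens default to chromosome 1 at the column index.
#'   Rows are `sample_id`, `phenotype` (`case`/`control`), then genotypes
#'   in `{0,1,2,NA}`. Ragged rows and symbols outside the alphabet are
#'   parse errors naming the offending row and column.
#' @return A [genotype_panel].
#' @export
read_text_matrix <- function(path, cohort = NA_character_) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("parse error: need a header and >=1 sample row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (length(header) < 3L) {
    stop("parse error: header must be sample_id, phenotype, variants...")
  }
  vtok <- header[-(1:2)]
  s <- length(vtok)
  parsed <- strsplit(vtok, ":", fixed = TRUE)
  has_map <- vapply(parsed, length, 1L) >= 3L
  variants <- data.frame(
    chrom = ifelse(has_map,
                   suppressWarnings(as.integer(vapply(parsed, `[`, "", 1L))),
                   1L),
    id = ifelse(has_map,
                vapply(parsed, function(x) paste(x[-(1:2)], collapse = ":"), ""),
                vtok),
    pos_bp = ifelse(has_map,
                    suppressWarnings(as.integer(vapply(parsed, `[`, "", 2L))),
                    seq_len(s)),
    allele_a = "A", allele_b = "B",
    stringsAsFactors = FALSE
  )
  if (anyNA(variants$chrom) || anyNA(variants$pos_bp)) {
    stop("parse error: malformed chrom:pos:id variant token in header")
  }

  rows <- fields[-1]
  n <- length(rows)
  genotypes <- matrix(NA_integer_, nrow = n, ncol = s)
  ids <- character(n)
  phen <- character(n)
  for (i in seq_len(n)) {
    f <- rows[[i]]
    if (length(f) != s + 2L) {
      stop("parse error: row ", i + 1L, " has ", length(f),
           " fields, expected ", s + 2L)
    }
    ids[i] <- f[1]
    phen[i] <- f[2]
    for (j in seq_len(s)) {
      tok <- f[j + 2L]
      if (tok == "NA") next
      if (!tok %in% c("0", "1", "2")) {
        stop("parse error: symbol '", tok, "' outside {0,1,2,NA} at row ",
             i + 1L, ", column ", j + 2L)
      }
      genotypes[i, j] <- as.integer(tok)
    }
  }
  if (!all(phen %in% c("case", "control"))) {
    stop("parse error: phenotype column must be 'case' or 'control'")
  }
  genotype_panel(genotypes, variants,
                 data.frame(id = ids, phenotype = phen, cohort = cohort,
                            stringsAsFactors = FALSE))
}

#' Write a genotype panel in the plain-text matrix dialect
#'
#' @param panel a [genotype_panel].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_text_matrix <- function(panel, path) {
  validate_panel(panel)
  if (n_samples(panel) == 0L || n_variants(panel) == 0L) {
    stop("empty panel: nothing to write")
  }
  v <- panel$variants
  header <- c("sample_id", "phenotype",
              paste(v$chrom, v$pos_bp, v$id, sep = ":"))
  g <- panel$genotypes
  body <- vapply(seq_len(nrow(g)), function(i) {
    paste(c(panel$samples$id[i], panel$samples$phenotype[i],
            ifelse(is.na(g[i, ]), "NA", as.character(g[i, ]))),
          collapse = "\t")
  }, "")
  writeLines(c(paste(header, collapse = "\t"), body), path)
  invisible(path)
}
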