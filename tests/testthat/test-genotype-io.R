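test_that("bed triplet round trip is the identity and deterministic", {
  panel <- random_panel(11, n = 20, s = 100)
  prefix <- file.path(withr::local_tempdir(), "rt")
  write_bed_triplet(panel, prefix)
  back <- read_bed_triplet(paste0(prefix, ".bed"))
  expect_identical(unname(back$genotypes), unname(panel$genotypes))
  expect_equal(back$variants, panel$variants, ignore_attr = TRUE)
  expect_equal(back$samples$id, panel$samples$id)
  expect_equal(back$samples$phenotype, panel$samples$phenotype)

  # second write of the re-read panel is byte-identical
  prefix2 <- file.path(withr::local_tempdir(), "rt2")
  write_bed_triplet(back, prefix2)
  expect_identical(readBin(paste0(prefix, ".bed"), "raw", 1e6),
                   readBin(paste0(prefix2, ".bed"), "raw", 1e6))
})

test_that("a crafted .bed byte decodes per the 2-bit little-endian layout", {
  # 0b11011000 packs, LSB pair first: 00 hom_a, 10 het, 01 missing, 11 hom_b
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "x.bed")
  con <- file(bed, "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0xd8)), con)
  close(con)
  writeLines("1\tsnp1\t0\t1000\tA\tB", file.path(dir, "x.bim"))
  writeLines(sprintf("s%d\ts%d\t0\t0\t0\t%d", 1:4, 1:4, c(1, 2, 1, 2)),
             file.path(dir, "x.fam"))
  panel <- read_bed_triplet(bed)
  expect_identical(unname(panel$genotypes[, 1]), c(0L, 1L, NA, 2L))
})

test_that("1 sample x 1 variant writes exactly 4 bytes (3 magic + 1 data)", {
  panel <- make_panel(matrix(0L, 1, 1))
  prefix <- file.path(withr::local_tempdir(), "tiny")
  write_bed_triplet(panel, prefix)
  expect_identical(file.size(paste0(prefix, ".bed")), 4)
})

test_that("malformed .bed inputs raise format/truncation/map errors", {
  dir <- withr::local_tempdir()
  panel <- random_panel(12, n = 5, s = 10)
  prefix <- file.path(dir, "p")
  write_bed_triplet(panel, prefix)

  # magic mismatch
  raw <- readBin(paste0(prefix, ".bed"), "raw", 1e6)
  bad <- file.path(dir, "bad.bed")
  writeBin(c(as.raw(c(0x00, 0x00)), raw[-(1:2)]), bad)
  expect_error(read_bed_triplet(bad, paste0(prefix, ".bim"),
                                paste0(prefix, ".fam")), "magic")

  # individual-major mode rejected
  writeBin(c(as.raw(c(0x6c, 0x1b, 0x00)), raw[-(1:3)]), bad)
  expect_error(read_bed_triplet(bad, paste0(prefix, ".bim"),
                                paste0(prefix, ".fam")), "individual-major")

  # truncated body
  writeBin(raw[seq_len(length(raw) - 1L)], bad)
  expect_error(read_bed_triplet(bad, paste0(prefix, ".bim"),
                                paste0(prefix, ".fam")), "truncation")

  # unsorted positions within a chromosome
  bim <- read.table(paste0(prefix, ".bim"), sep = "\t")
  bim$V4 <- rev(bim$V4)
  write.table(bim, file.path(dir, "bad.bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  expect_error(read_bed_triplet(paste0(prefix, ".bed"),
                                file.path(dir, "bad.bim"),
                                paste0(prefix, ".fam")), "map error")

  # phenotype column all -9
  fam <- read.table(paste0(prefix, ".fam"), sep = "\t")
  fam$V6 <- -9L
  write.table(fam, file.path(dir, "bad.fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  expect_error(read_bed_triplet(paste0(prefix, ".bed"),
                                paste0(prefix, ".bim"),
                                file.path(dir, "bad.fam")),
               "phenotype unassigned")
})

test_that("writing an empty panel is an error", {
  panel <- random_panel(13, n = 3, s = 5)
  expect_error(write_bed_triplet(panel[, integer(0)], tempfile()), "empty")
  expect_error(write_text_matrix(panel[integer(0), ], tempfile()), "empty")
})

test_that("text dialect round trips and matches the bed encoding", {
  panel <- random_panel(14, n = 10, s = 40)
  dir <- withr::local_tempdir()
  write_text_matrix(panel, file.path(dir, "p.txt"))
  write_bed_triplet(panel, file.path(dir, "p"))
  from_text <- read_text_matrix(file.path(dir, "p.txt"))
  from_bed <- read_bed_triplet(file.path(dir, "p.bed"))
  expect_identical(unname(from_text$genotypes), unname(from_bed$genotypes))
  expect_equal(from_text$variants$chrom, from_bed$variants$chrom)
  expect_equal(from_text$variants$pos_bp, from_bed$variants$pos_bp)
  expect_equal(from_text$samples$id, from_bed$samples$id)
})

test_that("text parser reports bad symbols and ragged rows by position", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "bad.txt")
  writeLines(c("sample_id\tphenotype\tv1\tv2\tv3",
               "s1\tcase\t0\t1\t2",
               "s2\tcontrol\t0\t3\t1"), f)
  expect_error(read_text_matrix(f), "symbol '3'.*row 3.*column 4")
  writeLines(c("sample_id\tphenotype\tv1\tv2\tv3",
               "s1\tcase\t0\t1"), f)
  expect_error(read_text_matrix(f), "row 2")
})

test_that("a literal 2-sample, 3-variant block loads with right dimensions", {
  f <- file.path(withr::local_tempdir(), "lit.txt")
  writeLines(c("sample_id\tphenotype\tv1\tv2\tv3",
               "s1\tcase\t0\tNA\t2",
               "s2\tcontrol\t1\t2\t0"), f)
  panel <- read_text_matrix(f)
  expect_equal(dim(panel), c(2L, 3L))
  expect_identical(unname(panel$genotypes[1, ]), c(0L, NA, 2L))
})

test_that("decoding is position-stable: sample permutation commutes with IO", {
  panel <- random_panel(15, n = 9, s = 30)
  perm <- c(4L, 1L, 9L, 2L, 8L, 3L, 6L, 7L, 5L)
  dir <- withr::local_tempdir()
  write_bed_triplet(panel[perm, ], file.path(dir, "a"))
  write_bed_triplet(panel, file.path(dir, "b"))
  a <- read_bed_triplet(file.path(dir, "a.bed"))
  b <- read_bed_triplet(file.path(dir, "b.bed"))[perm, ]
  expect_identical(unname(a$genotypes), unname(b$genotypes))
  expect_identical(a$samples$id, b$samples$id)
})
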