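test_that("indicator rasterisation is exact and round-trips", {
  panel <- make_panel(matrix(0L, 3, 120))
  segs <- data.frame(
    sample_id = c("s001", "s002"), phenotype = c("case", "control"),
    chrom = 1L, start_bp = c(10L, 11L) * 15000L,
    end_bp = c(82L, 90L) * 15000L,
    start_snp = c(10L, 11L), end_snp = c(83L, 91L),
    n_snps = c(73L, 80L), length_kb = 0, n_het = 0L, n_missing = 0L,
    stringsAsFactors = FALSE
  )
  m <- build_indicator(segs, panel)
  expect_equal(sum(m[1, ]), 73)
  expect_equal(which(m[1, ] == 1L), 10:82)
  expect_equal(sum(m[3, ]), 0)

  # rasterise then vectorise recovers the intervals
  runs <- rle(m[2, ])
  expect_equal(sum(m[2, ]), 80)
  expect_equal(which(m[2, ] == 1L)[1], 11)

  bad <- segs
  bad$end_snp[1] <- 200L
  expect_error(build_indicator(bad, panel), "consistency")
})

test_that("a shared run below the carrier threshold yields no regions", {
  panel <- make_panel(matrix(0L, 9, 150))
  m <- matrix(0L, 9, 150)
  m[, 20:119] <- 1L          # 9 identical carriers of a 100-SNP run
  expect_equal(nrow(consensus_regions(m, panel, min_carriers = 10,
                                      min_snps = 73)), 0L)
})

test_that("hand-traced consensus example: one region, twelve carriers", {
  # 12 samples share an 80-SNP run; scattered private runs elsewhere
  panel <- make_panel(matrix(0L, 15, 400))
  m <- matrix(0L, 15, 400)
  m[1:12, 101:180] <- 1L
  m[13, 1:90] <- 1L
  m[14, 201:300] <- 1L
  m[15, 320:400] <- 1L
  regs <- consensus_regions(m, panel, min_carriers = 10, min_snps = 73)
  expect_equal(nrow(regs), 1L)
  expect_equal(regs$start_snp, 101L)
  expect_equal(regs$end_snp, 181L)
  expect_equal(regs$n_snps, 80L)
  expect_setequal(regs$carriers[[1]], sprintf("s%03d", 1:12))
})

test_that("consensus is a fixpoint: rerunning on survivors changes nothing", {
  for (seed in 71:75) {
    set.seed(seed)
    panel <- make_panel(matrix(0L, 25, 300))
    m <- matrix(0L, 25, 300)
    for (i in 1:25) {
      n_runs <- sample(0:3, 1)
      for (k in seq_len(n_runs)) {
        a <- sample(250, 1)
        m[i, a:min(300, a + sample(30:120, 1))] <- 1L
      }
    }
    regs <- consensus_regions(m, panel, min_carriers = 5, min_snps = 40)
    # survivor matrix: restrict m to region footprints per carrier
    surv <- matrix(0L, 25, 300)
    for (r in seq_len(nrow(regs))) {
      rows <- match(regs$carriers[[r]], panel$samples$id)
      span <- regs$start_snp[r]:(regs$end_snp[r] - 1L)
      surv[rows, span] <- m[rows, span]
    }
    regs2 <- consensus_regions(surv, panel, min_carriers = 5, min_snps = 40)
    expect_equal(regs2[, names(regs2) != "carriers"],
                 regs[, names(regs) != "carriers"])
    # defining property: every region SNP has >= min_carriers carriers
    for (r in seq_len(nrow(regs))) {
      span <- regs$start_snp[r]:(regs$end_snp[r] - 1L)
      expect_true(all(colSums(surv[, span, drop = FALSE]) >= 5))
    }
  }
})

test_that("raising thresholds never enlarges or adds regions", {
  set.seed(76)
  panel <- make_panel(matrix(0L, 30, 300))
  m <- matrix(0L, 30, 300)
  for (i in 1:30) {
    a <- sample(200, 1)
    m[i, a:(a + sample(50:99, 1))] <- 1L
  }
  base <- consensus_regions(m, panel, min_carriers = 5, min_snps = 40)
  stricter_c <- consensus_regions(m, panel, min_carriers = 8, min_snps = 40)
  stricter_s <- consensus_regions(m, panel, min_carriers = 5, min_snps = 60)
  expect_lte(nrow(stricter_c), nrow(base))
  expect_lte(nrow(stricter_s), nrow(base))
  expect_lte(sum(stricter_c$n_snps), sum(base$n_snps))
  expect_lte(sum(stricter_s$n_snps), sum(base$n_snps))
})

test_that("fixpoint sheds cascade carriers that single-pass mode keeps", {
  # masking sub-threshold columns shortens sample 4's run in two stages;
  # only the fixpoint propagates the second stage, so sample 4 remains a
  # carrier in single-pass mode but not under the fixpoint
  panel <- make_panel(matrix(0L, 6, 200))
  m <- matrix(0L, 6, 200)
  m[1:3, 1:100] <- 1L
  m[4, 81:180] <- 1L
  m[5, 101:180] <- 1L
  m[6, 101:149] <- 1L
  one <- consensus_regions(m, panel, min_carriers = 3, min_snps = 50,
                           single_pass = TRUE)
  fix <- consensus_regions(m, panel, min_carriers = 3, min_snps = 50)
  expect_equal(fix$start_snp, 1L)
  expect_equal(fix$end_snp, 101L)
  expect_equal(one$start_snp, 1L)
  expect_equal(one$end_snp, 101L)
  expect_setequal(fix$carriers[[1]], sprintf("s%03d", 1:3))
  expect_setequal(one$carriers[[1]], sprintf("s%03d", 1:4))
})

test_that("carrier table reports two-significant-figure percentages", {
  regs <- data.frame(region_id = "ROH1", chrom = 9L,
                     start_bp = 1L, end_bp = 2L, start_snp = 1L,
                     end_snp = 2L, n_snps = 1L, stringsAsFactors = FALSE)
  regs$carriers <- list(c(sprintf("case_%04d", 1:18)))
  samples <- data.frame(
    id = c(sprintf("case_%04d", 1:2282), sprintf("ctrl_%04d", 1:5197)),
    phenotype = rep(c("case", "control"), c(2282, 5197)),
    stringsAsFactors = FALSE
  )
  tab <- region_carrier_table(regs, samples)
  expect_equal(tab$n_case_carriers, 18L)
  expect_equal(tab$pct_cases, 0.79)
  expect_equal(tab$n_control_carriers, 0L)
  expect_equal(tab$pct_controls, 0)

  regs$carriers <- list(c("nobody"))
  expect_error(region_carrier_table(regs, samples), "consistency")
})
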