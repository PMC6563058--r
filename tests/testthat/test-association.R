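test_that("chi-square 2x2 test matches the closed-form oracle", {
  # equal carrier proportions: no association at all
  res <- chi2_region_test(10, 90, 20, 180)
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)
  expect_equal(res$odds_ratio, 1)

  # discovery chr9-style counts vs n(ad-bc)^2/((a+b)(c+d)(a+c)(b+d))
  a <- 18; b <- 2264; c_ <- 13; d <- 5184
  res <- chi2_region_test(a, b, c_, d)
  n <- a + b + c_ + d
  chi2_oracle <- n * (a * d - b * c_)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
  expect_equal(res$chi2, chi2_oracle, tolerance = 1e-10)
  expect_equal(res$p, pchisq(chi2_oracle, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(res$odds_ratio, a * d / (b * c_))

  # zero cell engages the Haldane-Anscombe correction
  res0 <- chi2_region_test(0, 100, 10, 90)
  expect_true(is.finite(res0$odds_ratio))
  expect_equal(res0$odds_ratio, (0.5 * 90.5) / (100.5 * 10.5))
  expect_error(chi2_region_test(-1, 5, 5, 5), "domain")
})

test_that("burden t-tests match the textbook Welch computation", {
  set.seed(81)
  summ <- data.frame(
    sample_id = sprintf("s%02d", 1:50),
    phenotype = rep(c("case", "control"), c(20, 30)),
    n_roh = c(rpois(20, 16), rpois(30, 15)),
    total_length_bp = c(rnorm(20, 2.3e8, 6e7), rnorm(30, 2.2e8, 6e7)),
    stringsAsFactors = FALSE
  )
  res <- burden_tests(summ)
  for (metric in c("n_roh", "total_length_bp")) {
    x <- summ[[metric]][summ$phenotype == "case"]
    y <- summ[[metric]][summ$phenotype == "control"]
    o <- oracle_welch(x, y)
    row <- res[res$metric == metric, ]
    expect_equal(row$t, o$t, tolerance = 1e-10)
    expect_equal(row$p, o$p, tolerance = 1e-10)
    expect_equal(row$mean_cases, mean(x))
    expect_equal(row$sd_controls, sd(y))
  }

  # identical groups: t = 0, p = 1
  same <- data.frame(sample_id = sprintf("s%02d", 1:20),
                     phenotype = rep(c("case", "control"), each = 10),
                     n_roh = rep(1:10, 2),
                     total_length_bp = rep(seq(1e6, 1e7, length.out = 10), 2),
                     stringsAsFactors = FALSE)
  res_same <- burden_tests(same)
  expect_equal(res_same$t, c(0, 0))
  expect_equal(res_same$p, c(1, 1))

  expect_error(burden_tests(summ[c(1, 21:40), ]), "two samples")
})

test_that("burden test p-values are uniform under the null", {
  set.seed(82)
  ps <- replicate(1000, {
    summ <- data.frame(
      sample_id = sprintf("s%02d", 1:60),
      phenotype = rep(c("case", "control"), each = 30),
      n_roh = rnorm(60, 15, 3),
      total_length_bp = 0,
      stringsAsFactors = FALSE
    )
    burden_tests(summ)$p[1]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("candidate selection is strict and sorted", {
  res <- data.frame(region_id = sprintf("ROH%d", 1:5),
                    p = c(0.02, 0.01, 0.0099, 0.5, 0.001),
                    stringsAsFactors = FALSE)
  sel <- select_candidates(res, 0.01)
  expect_equal(sel$region_id, c("ROH5", "ROH3"))
  expect_equal(nrow(select_candidates(res, 1e-4)), 0L)
})

test_that("region pairing reports chromosome-wise interval intersections", {
  disc <- data.frame(region_id = c("ROH296", "ROH100"),
                     chrom = c(9L, 2L),
                     start_bp = c(71.1e6, 10e6), end_bp = c(74.3e6, 12e6),
                     stringsAsFactors = FALSE)
  repl <- data.frame(region_id = c("ROH198", "ROH7"),
                     chrom = c(9L, 2L),
                     start_bp = c(71.4e6, 30e6), end_bp = c(74.3e6, 31e6),
                     stringsAsFactors = FALSE)
  ov <- merge_overlap(disc, repl)
  expect_equal(nrow(ov), 1L)       # chr2 regions are disjoint
  expect_equal(ov$discovery_id, "ROH296")
  expect_equal(ov$overlap_start_bp, 71.4e6)
  expect_equal(ov$overlap_end_bp, 74.3e6)

  # identical lists pair one-to-one with intersection = interval
  self <- merge_overlap(disc, disc)
  expect_equal(nrow(self), 2L)
  expect_equal(self$overlap_start_bp, self$discovery_start_bp)
  expect_equal(self$overlap_end_bp, self$discovery_end_bp)

  # same coordinates, different chromosome: no pair
  repl2 <- transform(disc, chrom = chrom + 1L)
  expect_equal(nrow(merge_overlap(disc, repl2)), 0L)
})

test_that("fixed-effects pooling follows the inverse-variance formulas", {
  t1 <- c(30, 170, 40, 360)
  m1 <- meta_fixed(list(t1))
  lo <- log(30 * 360 / (170 * 40))
  se <- sqrt(1 / 30 + 1 / 170 + 1 / 40 + 1 / 360)
  expect_equal(m1$pooled_log_or, lo)
  expect_equal(m1$pooled_se, se)

  # two identical studies: same estimate, SE shrinks by 1/sqrt(2)
  m2 <- meta_fixed(list(t1, t1))
  expect_equal(m2$pooled_log_or, lo)
  expect_equal(m2$pooled_se, se / sqrt(2))

  # pooling is order-invariant and pooled variance is harmonic
  t2 <- c(11, 867, 75, 7008)
  ab <- meta_fixed(list(t1, t2))
  ba <- meta_fixed(list(t2, t1))
  expect_equal(ab$pooled_log_or, ba$pooled_log_or)
  expect_equal(ab$pooled_se, 1 / sqrt(sum(ab$studies$weight)))
  expect_gte(ab$pooled_log_or, min(ab$studies$log_or))
  expect_lte(ab$pooled_log_or, max(ab$studies$log_or))

  # cross-check against metafor's fixed-effects model
  mf <- metafor::rma(
    ai = c(t1[1], t2[1]), bi = c(t1[2], t2[2]),
    ci = c(t1[3], t2[3]), di = c(t1[4], t2[4]),
    measure = "OR", method = "FE"
  )
  expect_equal(ab$pooled_log_or, as.numeric(mf$beta), tolerance = 1e-8)
  expect_equal(ab$pooled_se, mf$se, tolerance = 1e-8)
  expect_equal(ab$p, mf$pval, tolerance = 1e-8)

  # empty-margin study is excluded with a warning
  expect_warning(m3 <- meta_fixed(list(t1, c(0, 0, 5, 5))), "margin")
  expect_equal(m3$pooled_log_or, lo)
})

test_that("pooling two cohorts sharpens direction-consistent evidence", {
  p0 <- 0.005
  or_to_p <- function(or) or * p0 / (1 - p0 + or * p0)
  draw <- function(or1, or2) {
    a <- rbinom(1, 2282, or_to_p(or1)); c1 <- rbinom(1, 5197, p0)
    a2 <- rbinom(1, 878, or_to_p(or2)); c2 <- rbinom(1, 7083, p0)
    list(t1 = c(a, 2282 - a, c1, 5197 - c1),
         t2 = c(a2, 878 - a2, c2, 7083 - c2))
  }
  or_hat <- function(tb) tb[1] * tb[4] / (tb[2] * tb[3])

  # comparable true effects: the pooled p beats both per-study p-values
  # for most direction-consistent draws
  set.seed(83)
  wins <- replicate(60, {
    d <- draw(1.5, 1.5)
    if (or_hat(d$t1) <= 1 || or_hat(d$t2) <= 1) return(NA)
    mm <- meta_fixed(list(d$t1, d$t2))
    p1 <- chi2_region_test(d$t1[1], d$t1[2], d$t1[3], d$t1[4])$p
    p2 <- chi2_region_test(d$t2[1], d$t2[2], d$t2[3], d$t2[4])$p
    mm$p < min(p1, p2)
  })
  expect_gt(mean(wins, na.rm = TRUE), 0.5)

  # strong discovery (OR 3) with weak replication (OR 1.2): pooling
  # always tightens the standard error and beats the replication p
  set.seed(84)
  for (rep in 1:10) {
    d <- draw(3, 1.2)
    if (any(c(d$t1, d$t2) == 0)) next
    mm <- meta_fixed(list(d$t1, d$t2))
    expect_lt(mm$pooled_se, min(mm$studies$se))
    p2 <- chi2_region_test(d$t2[1], d$t2[2], d$t2[3], d$t2[4])$p
    if (or_hat(d$t1) > 1 && or_hat(d$t2) > 1) expect_lt(mm$p, p2)
  }
})

test_that("cumulative curves are non-increasing survival fractions", {
  panel <- make_panel(matrix(0L, 4, 10),
                      phenotype = c("case", "case", "control", "control"))
  segs <- data.frame(
    sample_id = c("s001", "s002", "s003"),
    phenotype = c("case", "case", "control"),
    chrom = 1L,
    start_bp = c(0, 0, 0), end_bp = c(5e6, 2e6, 5e6),
    start_snp = 1L, end_snp = 2L, n_snps = 1L, length_kb = 0,
    n_het = 0L, n_missing = 0L, stringsAsFactors = FALSE
  )
  curve <- cumulative_curve(segs, panel)
  case <- curve[curve$phenotype == "case", ]
  ctrl <- curve[curve$phenotype == "control", ]
  # every sample with an ROH appears at the minimum observed length
  expect_equal(case$fraction[1], 1)       # both cases have an ROH
  expect_equal(ctrl$fraction[1], 0.5)     # one control of two
  # step down beyond 2 Mb for cases; flat for the 5 Mb control
  expect_equal(case$fraction, c(1, 0.5))
  expect_equal(ctrl$fraction, c(0.5, 0.5))
  expect_true(all(diff(case$fraction) <= 0))
  expect_true(all(diff(ctrl$fraction) <= 0))
})
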