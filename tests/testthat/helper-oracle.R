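# Independent reference implementations used as oracles. Deliberately
# literal and loop-based; they share no code with the package internals.

# exhaustive sliding-window ROH scanner: scores every window by direct
# summation, computes per-SNP hit fractions by enumerating covering
# windows, walks runs explicitly
oracle_call_roh <- function(panel, params) {
  out <- list()
  v <- panel$variants
  for (cc in unique(v$chrom)) {
    cols <- which(v$chrom == cc)
    pos <- v$pos_bp[cols]
    s <- length(cols)
    w <- params$window_snps
    if (s < w) next
    n_win <- s - w + 1L
    for (si in seq_len(nrow(panel$genotypes))) {
      g <- panel$genotypes[si, cols]
      hom_win <- logical(n_win)
      for (j in seq_len(n_win)) {
        win <- g[j:(j + w - 1L)]
        hom_win[j] <- sum(win == 1L, na.rm = TRUE) <= params$window_het_max &&
          sum(is.na(win)) <= params$window_missing_max
      }
      in_roh <- logical(s)
      for (i in seq_len(s)) {
        js <- max(1L, i - w + 1L):min(i, n_win)
        frac <- sum(hom_win[js]) / length(js)
        in_roh[i] <- frac >= params$snp_hit_threshold
      }
      i <- 1L
      while (i <= s) {
        if (!in_roh[i]) {
          i <- i + 1L
          next
        }
        j <- i
        while (j + 1L <= s && in_roh[j + 1L] &&
               pos[j + 1L] - pos[j] <= params$max_gap_kb * 1000) {
          j <- j + 1L
        }
        a <- i
        b <- j
        while (a <= b && (is.na(g[a]) || g[a] == 1L)) a <- a + 1L
        while (b >= a && (is.na(g[b]) || g[b] == 1L)) b <- b - 1L
        if (a <= b) {
          n_snp <- b - a + 1L
          span_kb <- (pos[b] - pos[a]) / 1000
          if (n_snp >= params$min_segment_snps &&
              span_kb >= params$min_segment_kb &&
              span_kb / n_snp <= params$min_density_kb_per_snp) {
            out[[length(out) + 1L]] <- data.frame(
              sample_id = panel$samples$id[si], chrom = cc,
              start_snp = cols[a], end_snp = cols[b] + 1L
            )
          }
        }
        i <- j + 1L
      }
    }
  }
  if (!length(out)) {
    return(data.frame(sample_id = character(), chrom = integer(),
                      start_snp = integer(), end_snp = integer()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$sample_id, res$chrom, res$start_snp), ]
  rownames(res) <- NULL
  res
}

# exact-factorial enumeration of the conditional heterozygote-count
# distribution; valid for small n where factorial() stays finite
oracle_hwe_p <- function(n_hom_a, n_het, n_hom_b) {
  n <- n_hom_a + n_het + n_hom_b
  na <- 2 * n_hom_a + n_het          # copies of allele A
  nb <- 2 * n_hom_b + n_het
  r <- min(na, nb)
  hets <- seq(r %% 2, min(r, 2 * n - r), by = 2)
  prob <- sapply(hets, function(ab) {
    aa <- (r - ab) / 2
    bb <- n - aa - ab
    factorial(n) / (factorial(aa) * factorial(ab) * factorial(bb)) *
      2^ab * factorial(r) * factorial(2 * n - r) / factorial(2 * n)
  })
  obs <- prob[match(n_het, hets)]
  sum(prob[prob <= obs * (1 + 1e-9)])
}

# textbook Welch t-test from the defining formulas
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
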