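# One-command orchestration: simulate/load -> QC -> calibrate -> detect
# -> consensus -> associate per cohort, then candidate carry-over by
# coordinate overlap and fixed-effects meta-analysis across the two
# cohorts, with every stage output written as TSV under one run
# directory plus a manifest of row counts, seeds and checksums.

#' Read a pipeline run configuration from YAML
#'
#' @param path YAML file with top-level keys `seed`, `output_dir`,
#'   optional `qc` and `candidate_p_max`, and a `cohorts` block with
#'   `discovery` and optionally `replication` entries; each cohort names
#'   either a `bed` prefix to load or a `simulate` block of
#'   [simulation_config()] fields, plus `min_segment_snps`,
#'   `min_carriers` and optional `roh` parameter overrides.
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$cohorts$discovery)) {
    stop("config error: a 'discovery' cohort block is required")
  }
  cfg
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

cohort_panel <- function(spec, name, default_seed) {
  if (!is.null(spec$bed)) {
    read_bed_triplet(paste0(spec$bed, ".bed"), cohort = name)
  } else if (!is.null(spec$simulate)) {
    args <- spec$simulate
    if (is.null(args$seed)) args$seed <- default_seed
    if (!is.null(args$planted_regions)) {
      args$planted_regions <- lapply(args$planted_regions, as.list)
    }
    sim <- simulate_panel(do.call(simulation_config, args))
    sim$panel$samples$cohort <- name
    sim
  } else {
    stop("cohort '", name, "' must give either 'bed' or 'simulate'")
  }
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

run_cohort <- function(spec, name, qc_cfg, out_dir, default_seed) {
  res <- list(name = name)

  loaded <- run_stage(paste0(name, ":load"),
                      cohort_panel(spec, name, default_seed))
  if (is.list(loaded) && !inherits(loaded, "genotype_panel")) {
    res$panel <- loaded$panel
    res$truth <- loaded$truth
  } else {
    res$panel <- loaded
  }

  qc <- run_stage(paste0(name, ":qc"), do.call(apply_qc, c(
    list(panel = res$panel),
    qc_cfg[intersect(names(qc_cfg),
                     c("sample_call_rate_min", "min_call_rate", "maf_min",
                       "hwe_alpha"))]
  )))
  res$panel <- qc$panel
  res$qc_report <- qc$report

  res$calibration <- run_stage(paste0(name, ":calibrate"),
                               calibrate_min_length(res$panel))

  min_snps <- spec$min_segment_snps
  if (is.null(min_snps)) min_snps <- res$calibration$adjusted_min_length
  params_args <- c(list(min_segment_snps = min_snps),
                   spec$roh[intersect(names(spec$roh),
                                      setdiff(names(formals(roh_params)),
                                              "min_segment_snps"))])
  params <- do.call(roh_params, params_args)
  res$params <- params

  res$segments <- run_stage(paste0(name, ":detect"),
                            call_roh(res$panel, params))
  res$summary <- per_sample_summary(res$segments, res$panel)

  min_carriers <- if (is.null(spec$min_carriers)) 10 else spec$min_carriers
  res$regions <- run_stage(paste0(name, ":consensus"), consensus_regions(
    build_indicator(res$segments, res$panel), res$panel,
    min_carriers = min_carriers, min_snps = min_snps
  ))

  res$burden <- run_stage(paste0(name, ":burden"),
                          burden_tests(res$summary))
  res$association <- run_stage(paste0(name, ":associate"),
                               region_association(res$regions,
                                                  res$panel$samples))
  res$curve <- cumulative_curve(res$segments, res$panel)

  pre <- file.path(out_dir, name)
  res$files <- c(
    write_tsv(res$segments, paste0(pre, "_segments.tsv")),
    write_tsv(res$summary, paste0(pre, "_sample_summary.tsv")),
    write_regions_tsv(res$regions, res$panel$samples,
                      paste0(pre, "_regions.tsv")),
    write_tsv(res$burden, paste0(pre, "_burden.tsv")),
    write_tsv(res$association, paste0(pre, "_association.tsv")),
    write_tsv(res$curve, paste0(pre, "_cumulative_curve.tsv")),
    write_calibration(res$calibration, paste0(pre, "_calibration.txt")),
    write_qc_report(res$qc_report, paste0(pre, "_qc_report.tsv"))
  )
  res
}

#' Run the whole homozygosity analysis pipeline
#'
#' Executes, per cohort: panel load or simulation, QC, minimum-length
#' calibration, ROH calling, consensus-region construction, burden and
#' per-region association tests. With a replication cohort, discovery
#' candidates (p below `candidate_p_max`) are carried over by coordinate
#' overlap and each overlapping pair is pooled by fixed-effects
#' inverse-variance meta-analysis. All stage outputs are written as TSV
#' under `output_dir`, with a manifest listing seeds, row counts and
#' file checksums. Identical configuration and seed give byte-identical
#' TSV outputs.
#'
#' @param config configuration list (see [read_run_config()]) or a path
#'   to a YAML file.
#' @return Invisibly, a list with per-cohort results (`discovery`,
#'   `replication`), the `candidates` table, the `overlap` pairing, the
#'   Table-2-style `meta_table`, and the manifest path.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- if (is.null(config$output_dir)) "." else config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  qc_cfg <- if (is.null(config$qc)) list() else config$qc
  p_max <- if (is.null(config$candidate_p_max)) 0.01 else
    config$candidate_p_max

  disc <- run_cohort(config$cohorts$discovery, "discovery", qc_cfg,
                     out_dir, stage_seed(seed, 101L))
  result <- list(discovery = disc)

  result$candidates <- select_candidates(disc$association, p_max)
  files <- c(disc$files,
             write_tsv(result$candidates,
                       file.path(out_dir, "discovery_candidates.tsv")))

  if (!is.null(config$cohorts$replication)) {
    repl <- run_cohort(config$cohorts$replication, "replication", qc_cfg,
                       out_dir, stage_seed(seed, 102L))
    result$replication <- repl
    result$overlap <- run_stage("overlap",
                                merge_overlap(result$candidates,
                                              repl$regions))
    result$meta_table <- run_stage("meta",
                                   meta_table(result$overlap,
                                              disc$association,
                                              repl$association))
    files <- c(files, repl$files,
               write_tsv(result$overlap,
                         file.path(out_dir, "region_overlap.tsv")),
               write_tsv(result$meta_table,
                         file.path(out_dir, "meta_results.tsv")))
  }

  manifest <- file.path(out_dir, "manifest.txt")
  counts <- c(
    discovery_segments = nrow(disc$segments),
    discovery_regions = nrow(disc$regions),
    discovery_candidates = nrow(result$candidates),
    replication_segments = if (!is.null(result$replication))
      nrow(result$replication$segments) else NA,
    replication_regions = if (!is.null(result$replication))
      nrow(result$replication$regions) else NA,
    meta_rows = if (!is.null(result$meta_table))
      nrow(result$meta_table) else NA
  )
  sums <- tools::md5sum(files)
  writeLines(c(
    paste0("wgha version: ",
           as.character(utils::packageVersion("wgha"))),
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("seed: ", seed),
    paste0("candidate_p_max: ", p_max),
    "",
    "stage row counts:",
    paste0("  ", names(counts), ": ", counts),
    "",
    "output checksums:",
    paste0("  ", basename(names(sums)), "  ", sums)
  ), manifest)
  result$manifest <- manifest
  invisible(result)
}

# Table-2-style report: one row per overlapping discovery/replication
# pair, with per-cohort 2x2 counts and the pooled fixed-effects p
meta_table <- function(overlap, disc_assoc, repl_assoc) {
  rows <- lapply(seq_len(nrow(overlap)), function(i) {
    da <- disc_assoc[disc_assoc$region_id == overlap$discovery_id[i], ]
    ra <- repl_assoc[repl_assoc$region_id == overlap$replication_id[i], ]
    mm <- meta_fixed(list(
      c(da$n_case_carriers, da$n_case_noncarriers,
        da$n_control_carriers, da$n_control_noncarriers),
      c(ra$n_case_carriers, ra$n_case_noncarriers,
        ra$n_control_carriers, ra$n_control_noncarriers)
    ))
    data.frame(
      chrom = overlap$chrom[i],
      discovery_id = overlap$discovery_id[i],
      replication_id = overlap$replication_id[i],
      discovery_mb = sprintf("%.1f-%.1f", overlap$discovery_start_bp[i] / 1e6,
                             overlap$discovery_end_bp[i] / 1e6),
      replication_mb = sprintf("%.1f-%.1f",
                               overlap$replication_start_bp[i] / 1e6,
                               overlap$replication_end_bp[i] / 1e6),
      n_case_carriers_disc = da$n_case_carriers,
      n_control_carriers_disc = da$n_control_carriers,
      n_case_carriers_repl = ra$n_case_carriers,
      n_control_carriers_repl = ra$n_control_carriers,
      p_discovery = da$p, p_replication = ra$p,
      pooled_log_or = mm$pooled_log_or, p_meta = mm$p,
      stringsAsFactors = FALSE
    )
  })
  if (!length(rows)) {
    return(data.frame(chrom = integer(), discovery_id = character(),
                      replication_id = character(),
                      discovery_mb = character(),
                      replication_mb = character(),
                      n_case_carriers_disc = integer(),
                      n_control_carriers_disc = integer(),
                      n_case_carriers_repl = integer(),
                      n_control_carriers_repl = integer(),
                      p_discovery = numeric(), p_replication = numeric(),
                      pooled_log_or = numeric(), p_meta = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
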