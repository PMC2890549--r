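#' Pipeline run configuration
#'
#' Validated bundle of paths, thresholds and options consumed by
#' [run_all()]. Either supply input paths (`genotypes`, `peaks`,
#' `covariates`) for a real dataset, or a `simulation` block
#' ([sim_config()]) to generate one.
#'
#' @param out_dir output directory.
#' @param genotypes,peaks,covariates input paths (ignored when simulating).
#' @param simulation a [sim_config()] or `NULL`.
#' @param marker_snp_ids transcribed marker SNPs (taken from the simulation
#'   config when simulating).
#' @param ase_lower,ase_upper ASE call thresholds (must bracket 1).
#' @param r2_threshold,maf_threshold tagging parameters.
#' @param run_tagging run the tag-selection stage (default TRUE).
#' @param drop_uninformative passed to [assoc_scan()].
#' @param seed master seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       genotypes = NULL, peaks = NULL, covariates = NULL,
                       simulation = NULL,
                       marker_snp_ids = if (!is.null(simulation)) simulation$marker_snp_ids,
                       ase_lower = 0.67, ase_upper = 1.5,
                       r2_threshold = 0.8, maf_threshold = 0.05,
                       run_tagging = TRUE, drop_uninformative = FALSE,
                       seed = 1L) {
  if (!(ase_lower < 1 && 1 < ase_upper))
    stop_validation("config field 'ase_lower'/'ase_upper': need ase_lower < 1 < ase_upper")
  if (r2_threshold <= 0 || r2_threshold > 1)
    stop_validation("config field 'r2_threshold': must be in (0, 1]")
  if (is.null(simulation)) {
    for (p in c(genotypes = genotypes, peaks = peaks, covariates = covariates))
      if (is.null(p) || !file.exists(p))
        stop_validation("config field 'paths': input file '%s' missing", p)
    if (is.null(marker_snp_ids))
      stop_validation("config field 'marker_snp_ids': required for non-simulation runs")
  } else stopifnot(inherits(simulation, "sim_config"))
  structure(list(out_dir = out_dir, genotypes = genotypes, peaks = peaks,
                 covariates = covariates, simulation = simulation,
                 marker_snp_ids = marker_snp_ids,
                 ase_lower = ase_lower, ase_upper = ase_upper,
                 r2_threshold = r2_threshold, maf_threshold = maf_threshold,
                 run_tagging = run_tagging,
                 drop_uninformative = drop_uninformative,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages: (optional) simulate and write a cohort, call the ASE phenotype,
#' summarize the cohort with clinical Fisher contrasts, (optional) select
#' tag SNPs, and scan every SNP for allelic association. Artifacts written
#' to `out_dir`: `ase_calls.tsv`, `ase_per_snp.tsv`, `summary.tsv`,
#' `fisher.tsv`, `tags.tsv`, `proxies.tsv`, `coverage.json`, `assoc.tsv`,
#' `report.txt` and `manifest.json`. Identical config plus inputs yield an
#' identical output tree.
#'
#' @param config a [run_config()].
#' @return invisibly, list with the in-memory stage results.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- character(0)

  if (!is.null(config$simulation)) {
    sim <- simulate_cohort(config$simulation)
    sim_dir <- file.path(config$out_dir, "simulated")
    paths <- write_cohort(sim, sim_dir)
    geno <- sim$genotypes
    peaks <- sim$peaks
    covariates <- sim$covariates
    markers <- config$simulation$marker_snp_ids
    inputs <- paths
  } else {
    geno <- read_genotypes(config$genotypes)
    peaks <- read_peaks(config$peaks)
    covariates <- read_covariates(config$covariates)
    markers <- config$marker_snp_ids
    inputs <- c(config$genotypes, config$peaks, config$covariates)
  }

  calls <- call_cohort(peaks, geno, markers,
                       lower = config$ase_lower, upper = config$ase_upper)
  summary <- summarize_cohort(calls, covariates)

  tags <- NULL
  if (config$run_tagging)
    tags <- greedy_tag(geno, r2_threshold = config$r2_threshold,
                       maf_threshold = config$maf_threshold)

  scan <- assoc_scan(geno, calls, snp_ids = setdiff(colnames(geno), markers),
                     drop_uninformative = config$drop_uninformative)

  ## ---- write artifacts ----
  wtsv <- function(df, name) {
    utils::write.table(df, file.path(config$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wtsv(calls$calls, "ase_calls.tsv")
  wtsv(calls$per_snp, "ase_per_snp.tsv")
  wtsv(summary$counts, "summary.tsv")
  wtsv(summary$fisher, "fisher.tsv")
  if (!is.null(tags)) {
    wtsv(data.frame(tag = tags$tags), "tags.tsv")
    wtsv(tags$proxy_map, "proxies.tsv")
    cov_rep <- coverage_report(tags)
    jsonlite::write_json(cov_rep[c("mean_r2", "n_common", "n_tags",
                                   "n_covered_at_threshold")],
                         file.path(config$out_dir, "coverage.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  wtsv(scan, "assoc.tsv")
  writeLines(report_text(summary, scan), file.path(config$out_dir, "report.txt"))

  manifest <- list(
    tool = "aseassoc",
    version = as.character(utils::packageVersion("aseassoc")),
    seed = config$seed,
    thresholds = list(ase_lower = config$ase_lower, ase_upper = config$ase_upper,
                      r2 = config$r2_threshold, maf = config$maf_threshold),
    config_hash = unname(tools::md5sum(
      local({ f <- tempfile(); jsonlite::write_json(
        config[setdiff(names(config), c("simulation", "out_dir", "genotypes",
                                        "peaks", "covariates"))],
        f, auto_unbox = TRUE, force = TRUE); f }))),
    input_checksums = as.list(stats::setNames(unname(tools::md5sum(inputs)),
                                              basename(inputs))),
    rows = list(peaks = nrow(peaks), subjects = nrow(geno),
                snps = ncol(geno), assoc = nrow(scan)),
    n_ase_positive = summary$n_positive)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(calls = calls, summary = summary, tags = tags, scan = scan,
                 manifest = manifest))
}

#' Render a human-readable run report
#'
#' Demographics stratified by ASE status (percentages at 1 decimal,
#' half-up) followed by the association table (frequencies at 2 decimals,
#' odds ratios at 1 decimal, `"n/a"` where undefined).
#'
#' @param summary a `cohort_summary`.
#' @param scan an `assoc_scan`.
#' @return character vector of report lines.
#' @export
report_text <- function(summary, scan) {
  lines <- c(sprintf("Cohort: %d subjects; %d (%.1f%%) ASE positive",
                     summary$n, summary$n_positive, summary$prevalence_percent),
             "", "Demographics (n, % of cohort: ASE+ | ASE-)")
  for (i in seq_len(nrow(summary$counts))) {
    r <- summary$counts[i, ]
    lines <- c(lines, sprintf("  %-15s %-18s %3d (%4.1f%%) | %3d (%4.1f%%)",
                              r$covariate, r$level, r$n_ase_pos, r$pct_ase_pos,
                              r$n_ase_neg, r$pct_ase_neg))
  }
  lines <- c(lines, "", "Clinical contrasts (Fisher exact):")
  for (i in seq_len(nrow(summary$fisher)))
    lines <- c(lines, sprintf("  %-20s p = %.3f", summary$fisher$contrast[i],
                              summary$fisher$p[i]))
  fa <- format_assoc(scan)
  lines <- c(lines, "", "Association (allele-2 frequency ASE+ vs rest, chi-square):",
             sprintf("  %-12s %6s %6s %10s %6s", "SNP", "fASE", "frest", "P", "OR"))
  for (i in seq_len(nrow(fa)))
    lines <- c(lines, sprintf("  %-12s %6s %6s %10s %6s", fa$SNP[i],
                              fa$freq2_ASE[i], fa$freq2_rest[i], fa$P[i], fa$OR[i]))
  lines
}
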