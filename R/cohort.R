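#' Simulation configuration
#'
#' Bundles every knob of the synthetic-cohort generator. Defaults emulate the
#' study design the analysis modules target: 118 subjects genotyped at 19
#' locus SNPs plus four transcribed 3'-UTR marker SNPs, a cis-regulatory
#' allele at population frequency 0.10 that halves expression of the
#' haplotype carrying it (`effect_fold = 0.5`), an r-squared = 1 proxy SNP
#' planted next to it, and an allelic peak-area assay run as two independent
#' cDNA preparations each in duplicate, normalized against genomic DNA.
#'
#' With four markers at allele frequency 0.10 the chance a subject is
#' heterozygous for at least one transcribed marker (and hence assayable) is
#' about 0.55, so the expected fraction of the cohort called ASE-positive is
#' roughly 2(0.1)(0.9) x 0.55, i.e. the ~10% documented as
#' `target_prevalence`.
#'
#' @param n_subjects cohort size (default 118).
#' @param seed master seed; stage streams are derived via [derive_seed()].
#' @param locus_snp_ids,marker_snp_ids SNP identifiers; markers are the
#'   transcribed SNPs whose allelic peaks are measured.
#' @param causal_snp_id SNP whose allele 1 multiplies the expression of the
#'   haplotype carrying it by `effect_fold`.
#' @param proxy_snp_id SNP whose panel column is copied from the causal SNP
#'   (planted perfect proxy); `NA` to disable.
#' @param causal_freq,marker_freq target allele-1 frequencies.
#' @param n_haplotypes panel size (equifrequent haplotypes).
#' @param effect_fold expression multiplier for haplotypes carrying the
#'   causal allele (> 0; 1 = null).
#' @param sigma_gdna,sigma_cdna lognormal noise scale (sd of log area) per
#'   template.
#' @param n_preps,n_duplicates cDNA replicate design (preparations x
#'   duplicates).
#' @param baseline_area expected peak area, arbitrary fluorescence units.
#' @param gdna_per_slot if `TRUE` (default) one gDNA peak pair is emitted per
#'   replicate slot; if `FALSE` a single shared gDNA pair per subject-SNP.
#' @param covariate_distributions named list of category probability vectors
#'   for `sex`, `ethnicity`, `location`, `stage`, `family_history`.
#' @param target_prevalence documented expected ASE-positive fraction at
#'   these defaults (used by calibration checks, not by the generator).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 118L,
                       seed = 1L,
                       locus_snp_ids = sprintf("L%02d", 1:19),
                       marker_snp_ids = sprintf("M%d", 1:4),
                       causal_snp_id = "L07",
                       proxy_snp_id = "L08",
                       causal_freq = 0.10,
                       marker_freq = 0.10,
                       n_haplotypes = 100L,
                       effect_fold = 0.5,
                       sigma_gdna = 0.05,
                       sigma_cdna = 0.10,
                       n_preps = 2L,
                       n_duplicates = 2L,
                       baseline_area = 1000,
                       gdna_per_slot = TRUE,
                       covariate_distributions = default_covariate_distributions(),
                       target_prevalence = 0.10) {
  if (!is_count(n_subjects) || n_subjects < 1)
    stop_validation("config field 'n_subjects': must be a positive integer")
  if (effect_fold <= 0)
    stop_validation("config field 'effect_fold': must be > 0")
  if (sigma_gdna < 0 || sigma_cdna < 0)
    stop_validation("config field 'sigma_gdna'/'sigma_cdna': must be >= 0")
  if (!is_count(n_preps) || !is_count(n_duplicates) || n_preps * n_duplicates < 1)
    stop_validation("config field 'n_preps'/'n_duplicates': n_preps x n_duplicates must be >= 1")
  if (baseline_area <= 0)
    stop_validation("config field 'baseline_area': must be > 0")
  snp_ids <- c(locus_snp_ids, marker_snp_ids)
  if (anyDuplicated(snp_ids))
    stop_validation("config field 'locus_snp_ids'/'marker_snp_ids': SNP ids must be unique")
  if (length(marker_snp_ids) < 1)
    stop_validation("config field 'marker_snp_ids': at least one marker SNP required")
  if (!causal_snp_id %in% snp_ids)
    stop_validation("config field 'causal_snp_id': '%s' not among SNP ids", causal_snp_id)
  if (!is.na(proxy_snp_id) && !proxy_snp_id %in% snp_ids)
    stop_validation("config field 'proxy_snp_id': '%s' not among SNP ids", proxy_snp_id)
  if (causal_freq <= 0 || causal_freq >= 1)
    stop_validation("config field 'causal_freq': must be in (0, 1)")
  for (nm in names(covariate_distributions))
    check_prob_vector(covariate_distributions[[nm]],
                      sprintf("covariate_distributions$%s", nm))
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 locus_snp_ids = locus_snp_ids, marker_snp_ids = marker_snp_ids,
                 causal_snp_id = causal_snp_id, proxy_snp_id = proxy_snp_id,
                 causal_freq = causal_freq, marker_freq = marker_freq,
                 n_haplotypes = as.integer(n_haplotypes),
                 effect_fold = effect_fold,
                 sigma_gdna = sigma_gdna, sigma_cdna = sigma_cdna,
                 n_preps = as.integer(n_preps), n_duplicates = as.integer(n_duplicates),
                 baseline_area = baseline_area, gdna_per_slot = gdna_per_slot,
                 covariate_distributions = covariate_distributions,
                 target_prevalence = target_prevalence),
            class = "sim_config")
}

#' Default clinical covariate category probabilities
#'
#' Marginal category probabilities of a colorectal-cancer case series:
#' roughly balanced sex, two-thirds colon primaries, a predominantly
#' Caucasian cohort, and a stage distribution weighted toward II-IV.
#' Covariates are generated independently of ASE status (null clinical
#' association).
#' @return named list of named probability vectors.
#' @export
default_covariate_distributions <- function() {
  list(sex = c(Female = 0.47, Male = 0.53),
       ethnicity = c(Caucasian = 0.83, `African American` = 0.12,
                     Asian = 0.025, Hispanic = 0.025),
       location = c(Colon = 0.65, Rectum = 0.34, Both = 0.01),
       stage = c(I = 0.09, II = 0.255, III = 0.375, IV = 0.28),
       family_history = c(No = 0.645, Yes = 0.285, Unknown = 0.07))
}

#' Draw a diploid cohort from a haplotype panel
#'
#' Each subject is two independent draws from the panel's haplotype
#' distribution (Hardy-Weinberg); phase is retained.
#'
#' @param panel a [haplotype_panel()].
#' @param n number of subjects.
#' @param seed RNG seed for the draw.
#' @return an object of class `phased_cohort`: list with `subject_id`,
#'   allele matrices `hap_a` and `hap_b` (n x M, 0/1), `snp_ids`,
#'   `phase_known = TRUE`.
#' @export
draw_subjects <- function(panel, n, seed = 1L) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (!is_count(n) || n < 1) stop_validation("'n': must be a positive integer")
  set.seed(seed)
  idx_a <- sample.int(nrow(panel$haplotypes), n, replace = TRUE, prob = panel$frequencies)
  idx_b <- sample.int(nrow(panel$haplotypes), n, replace = TRUE, prob = panel$frequencies)
  ids <- sprintf("S%03d", seq_len(n))
  structure(list(subject_id = ids,
                 hap_a = panel$haplotypes[idx_a, , drop = FALSE],
                 hap_b = panel$haplotypes[idx_b, , drop = FALSE],
                 snp_ids = panel$snp_ids,
                 phase_known = TRUE),
            class = "phased_cohort")
}

#' Genotype matrix (0/1/2 allele-1 dosage) of a phased cohort
#' @param cohort a `phased_cohort`.
#' @return integer matrix, subjects x SNPs, with dimnames.
#' @export
cohort_genotypes <- function(cohort) {
  g <- cohort$hap_a + cohort$hap_b
  dimnames(g) <- list(cohort$subject_id, cohort$snp_ids)
  g
}

#' Per-haplotype expression levels under a cis-regulatory allele
#'
#' Baseline expression of each haplotype is 1.0; a haplotype carrying
#' allele 1 at the causal SNP is multiplied by `effect_fold`. A heterozygous
#' carrier therefore expresses its two haplotypes at (1, `effect_fold`),
#' while a homozygous carrier is reduced on both and shows no allelic
#' imbalance.
#'
#' @param cohort a `phased_cohort`.
#' @param causal_snp_id SNP id present in the cohort.
#' @param effect_fold positive expression multiplier.
#' @return n x 2 matrix with columns `expr_a`, `expr_b`.
#' @export
simulate_expression <- function(cohort, causal_snp_id, effect_fold) {
  if (!causal_snp_id %in% cohort$snp_ids)
    stop_validation("'causal_snp_id': '%s' not in cohort SNPs", causal_snp_id)
  if (effect_fold <= 0) stop_validation("'effect_fold': must be > 0")
  expr <- cbind(expr_a = ifelse(cohort$hap_a[, causal_snp_id] == 1, effect_fold, 1),
                expr_b = ifelse(cohort$hap_b[, causal_snp_id] == 1, effect_fold, 1))
  rownames(expr) <- cohort$subject_id
  expr
}

#' Simulate allelic peak-area measurements
#'
#' For every subject-marker pair where the subject is heterozygous, emits
#' gDNA and cDNA peak-area pairs in the replicate design of the config.
#' Expected gDNA areas are `baseline_area` for both alleles (one copy each);
#' expected cDNA areas are proportional to the expression level of the
#' haplotype carrying each allele. Every emitted area is the expected value
#' times multiplicative lognormal noise, `exp(N(0, sigma))`, with sigma per
#' template. Homozygous markers yield no rows (the assay cannot distinguish
#' the alleles).
#'
#' @param cohort a `phased_cohort`.
#' @param expression matrix from [simulate_expression()].
#' @param config a [sim_config()].
#' @param seed RNG seed for the noise stream.
#' @return data.frame with columns `subject_id`, `snp_id`, `template`
#'   (gDNA/cDNA), `prep`, `duplicate`, `area_allele0`, `area_allele1`.
#' @export
simulate_peaks <- function(cohort, expression, config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (config$baseline_area <= 0)
    stop_validation("config field 'baseline_area': must be > 0")
  set.seed(seed)
  rows <- vector("list", 0L)
  slots <- expand.grid(duplicate = seq_len(config$n_duplicates),
                       prep = seq_len(config$n_preps))[, c("prep", "duplicate")]
  for (i in seq_along(cohort$subject_id)) {
    for (s in config$marker_snp_ids) {
      a <- cohort$hap_a[i, s]; b <- cohort$hap_b[i, s]
      if (a + b != 1L) next                      # not heterozygous: uninformative
      ## expression of the haplotype carrying allele 0 / allele 1
      e0 <- if (a == 0L) expression[i, "expr_a"] else expression[i, "expr_b"]
      e1 <- if (a == 1L) expression[i, "expr_a"] else expression[i, "expr_b"]
      g_slots <- if (config$gdna_per_slot) slots else slots[1, , drop = FALSE]
      ng <- nrow(g_slots); nc <- nrow(slots)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = cohort$subject_id[i], snp_id = s,
        template = c(rep("gDNA", ng), rep("cDNA", nc)),
        prep = c(g_slots$prep, slots$prep),
        duplicate = c(g_slots$duplicate, slots$duplicate),
        area_allele0 = c(config$baseline_area *
                           exp(stats::rnorm(ng, 0, config$sigma_gdna)),
                         config$baseline_area * e0 *
                           exp(stats::rnorm(nc, 0, config$sigma_cdna))),
        area_allele1 = c(config$baseline_area *
                           exp(stats::rnorm(ng, 0, config$sigma_gdna)),
                         config$baseline_area * e1 *
                           exp(stats::rnorm(nc, 0, config$sigma_cdna))),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(subject_id = character(), snp_id = character(),
                      template = character(), prep = integer(),
                      duplicate = integer(), area_allele0 = numeric(),
                      area_allele1 = numeric()))
  do.call(rbind, rows)
}

#' Simulate clinical covariates
#'
#' Covariates are drawn independently of genotype and ASE status: the
#' simulator's clinical contrasts are null by construction. Age is
#' normal(60, 10) rounded and clamped to 35-84.
#'
#' @param n number of subjects.
#' @param distributions list as in [default_covariate_distributions()].
#' @param seed RNG seed.
#' @return data.frame with `subject_id`, `age`, `sex`, `ethnicity`,
#'   `location`, `stage`, `family_history`.
#' @export
simulate_covariates <- function(n, distributions = default_covariate_distributions(),
                                seed = 1L) {
  set.seed(seed)
  draw <- function(p) sample(names(p), n, replace = TRUE, prob = p)
  data.frame(subject_id = sprintf("S%03d", seq_len(n)),
             age = pmin(pmax(round(stats::rnorm(n, 60, 10)), 35), 84),
             sex = draw(distributions$sex),
             ethnicity = draw(distributions$ethnicity),
             location = draw(distributions$location),
             stage = draw(distributions$stage),
             family_history = draw(distributions$family_history),
             stringsAsFactors = FALSE)
}

#' Simulate a complete cohort
#'
#' Runs panel construction, subject draws, expression, peak measurements and
#' covariates off derived streams of the master seed, and records the ground
#' truth needed for recovery tests.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cohort` with elements `config`, `panel`,
#'   `cohort`, `genotypes`, `expression`, `peaks`, `covariates`, `truth`.
#'   `truth` holds `causal_snp_id`, `effect_fold` and a per-subject
#'   data.frame (`causal_het`, `n_het_markers`, `informative`, `true_fold`,
#'   `expected_call`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  panel <- build_panel(config)
  cohort <- draw_subjects(panel, config$n_subjects,
                          seed = derive_seed(config$seed, "subjects"))
  expr <- simulate_expression(cohort, config$causal_snp_id, config$effect_fold)
  peaks <- simulate_peaks(cohort, expr, config,
                          seed = derive_seed(config$seed, "noise"))
  covariates <- simulate_covariates(config$n_subjects,
                                    config$covariate_distributions,
                                    seed = derive_seed(config$seed, "covariates"))
  geno <- cohort_genotypes(cohort)
  causal_het <- geno[, config$causal_snp_id] == 1L
  n_het_markers <- rowSums(geno[, config$marker_snp_ids, drop = FALSE] == 1L)
  ## true allelic fold of a heterozygous-causal subject; 1 otherwise.
  ## A carrier is detectable at the canonical 1.5 / 0.67 thresholds when
  ## both assay orientations (fold and 1/fold) fall outside the negative
  ## band, i.e. fold <= 2/3 or fold >= 1.5.
  true_fold <- ifelse(causal_het, config$effect_fold, 1)
  detectable <- config$effect_fold <= 2 / 3 + 1e-12 || config$effect_fold >= 1.5
  truth <- list(causal_snp_id = config$causal_snp_id,
                proxy_snp_id = config$proxy_snp_id,
                effect_fold = config$effect_fold,
                subjects = data.frame(subject_id = cohort$subject_id,
                                      causal_het = causal_het,
                                      n_het_markers = n_het_markers,
                                      informative = n_het_markers > 0,
                                      true_fold = true_fold,
                                      expected_call = ifelse(
                                        n_het_markers == 0, "uninformative",
                                        ifelse(causal_het & detectable,
                                               "positive", "negative")),
                                      stringsAsFactors = FALSE, row.names = NULL))
  structure(list(config = config, panel = panel, cohort = cohort,
                 genotypes = geno, expression = expr, peaks = peaks,
                 covariates = covariates, truth = truth),
            class = "sim_cohort")
}

#' Write a simulated cohort to disk
#'
#' Emits the genotype matrix (both as a minimal VCF and a TSV dosage
#' matrix), the peak-area CSV, the covariate CSV and a JSON truth file; all
#' plain text, round-trippable through [read_genotypes()], [read_peaks()]
#' and [read_covariates()].
#'
#' @param sim a `sim_cohort` from [simulate_cohort()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, named character vector of file paths.
#' @export
write_cohort <- function(sim, out_dir) {
  stopifnot(inherits(sim, "sim_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_computation("cannot create directory '%s'", out_dir)
  paths <- c(vcf = file.path(out_dir, "genotypes.vcf"),
             tsv = file.path(out_dir, "genotypes.tsv"),
             peaks = file.path(out_dir, "peaks.csv"),
             covariates = file.path(out_dir, "covariates.csv"),
             truth = file.path(out_dir, "truth.json"))
  write_genotypes_vcf(sim$cohort, paths[["vcf"]])
  write_genotypes_tsv(sim$genotypes, paths[["tsv"]])
  utils::write.csv(sim$peaks, paths[["peaks"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$covariates, paths[["covariates"]], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paths)
}
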