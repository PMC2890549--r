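#' Normalized allelic-expression ratio
#'
#' The allelic ratio in cDNA divided by the matching ratio in genomic DNA:
#' `(cDNA common/rare) / (gDNA common/rare)`. The gDNA ratio corrects for
#' allele-specific assay bias, since both alleles are present in one copy
#' each in genomic DNA of a heterozygote.
#'
#' @param gdna,cdna one-row data.frames or named lists with fields
#'   `subject_id`, `snp_id`, `template`, `area_common`, `area_rare` (areas
#'   strictly positive, arbitrary fluorescence units).
#' @return positive numeric ratio.
#' @export
normalized_ratio <- function(gdna, cdna) {
  if (!identical(as.character(gdna$subject_id), as.character(cdna$subject_id)) ||
      !identical(as.character(gdna$snp_id), as.character(cdna$snp_id)))
    stop_validation("pairing error: gDNA and cDNA measurements must share subject_id and snp_id")
  if (!identical(as.character(gdna$template), "gDNA") ||
      !identical(as.character(cdna$template), "cDNA"))
    stop_validation("pairing error: templates must be gDNA and cDNA respectively")
  areas <- c(gdna$area_common, gdna$area_rare, cdna$area_common, cdna$area_rare)
  if (any(!is.finite(areas)) || any(areas <= 0))
    stop_validation("measurement error: peak areas must be strictly positive")
  (cdna$area_common / cdna$area_rare) / (gdna$area_common / gdna$area_rare)
}

#' Average replicate ratios
#'
#' Arithmetic mean of the per-replicate normalized ratios; the assay design
#' expects four (two cDNA preparations, each in duplicate), and a warning is
#' attached when fewer are available.
#'
#' @param ratios non-empty numeric vector of positive ratios.
#' @param expected_n replicate count the design calls for (default 4).
#' @return list with `mean_ratio` and `n_ratios`.
#' @export
replicate_mean <- function(ratios, expected_n = 4L) {
  if (length(ratios) == 0) stop_validation("replicate_mean: empty ratio list")
  if (any(!is.finite(ratios)) || any(ratios <= 0))
    stop_validation("replicate_mean: ratios must be positive and finite")
  if (length(ratios) < expected_n)
    warning(sprintf("incomplete replicates: %d of %d ratios available",
                    length(ratios), expected_n), call. = FALSE)
  list(mean_ratio = mean(ratios), n_ratios = length(ratios))
}

#' Classify a mean normalized ratio as ASE positive or negative
#'
#' A subject-SNP mean ratio is called positive for allele-specific
#' expression when it lies at or beyond either threshold (default
#' `>= 1.5` or `<= 0.67`, inclusive). Note the band is not exactly
#' reciprocal: 1/1.5 = 0.667 <= 0.67 is positive.
#'
#' @param mean_ratio positive numeric.
#' @param lower,upper thresholds (defaults 0.67 and 1.5).
#' @param inclusive use `>=`/`<=` (default) rather than strict inequalities.
#' @return `"positive"` or `"negative"`.
#' @export
classify_ase <- function(mean_ratio, lower = 0.67, upper = 1.5, inclusive = TRUE) {
  if (!is.finite(mean_ratio) || mean_ratio <= 0)
    stop_validation("classify_ase: mean_ratio must be positive")
  hit <- if (inclusive) mean_ratio >= upper || mean_ratio <= lower
         else           mean_ratio >  upper || mean_ratio <  lower
  if (hit) "positive" else "negative"
}

#' Is a subject informative for the allelic assay?
#'
#' A subject can be assayed only if heterozygous at one or more of the
#' transcribed marker SNPs; missing genotypes count as non-informative at
#' that marker.
#'
#' @param genotypes named vector of 0/1/2/NA dosages at the marker SNPs.
#' @return list with `informative` (logical) and `het_markers` (character).
#' @export
informative_subject <- function(genotypes) {
  het <- !is.na(genotypes) & genotypes == 1
  list(informative = any(het),
       het_markers = names(genotypes)[het])
}

#' Fraction of a cohort informative for the allelic assay
#'
#' @param genotypes subjects x SNPs dosage matrix.
#' @param marker_snp_ids transcribed marker SNP ids (columns of `genotypes`).
#' @return list with `n`, `n_informative`, `fraction`, `percent` (1 dp).
#' @export
informative_fraction <- function(genotypes, marker_snp_ids) {
  missing <- setdiff(marker_snp_ids, colnames(genotypes))
  if (length(missing))
    stop_validation("marker SNPs absent from genotypes: %s",
                    paste(missing, collapse = ", "))
  g <- genotypes[, marker_snp_ids, drop = FALSE]
  inf <- apply(g, 1, function(x) any(!is.na(x) & x == 1))
  list(n = nrow(g), n_informative = sum(inf), fraction = mean(inf),
       percent = round_half_up(100 * mean(inf), 1))
}

## Orientation rule: "common" allele at a marker is the higher-frequency
## allele among the cohort's genotypes at that SNP; ties go to allele 0
## (lexicographic). Returns "0" or "1".
common_allele <- function(genotype_column) {
  freq1 <- mean(genotype_column, na.rm = TRUE) / 2
  if (is.nan(freq1)) freq1 <- 0
  if (freq1 > 0.5) "1" else "0"
}

#' Call the ASE phenotype for a whole cohort
#'
#' For every subject and heterozygous marker SNP, pairs each cDNA replicate
#' slot with its gDNA slot (same prep and duplicate) when per-slot gDNA
#' exists, otherwise normalizes all cDNA slots by the mean gDNA ratio;
#' computes normalized common/rare ratios, averages them per SNP, and calls
#' the subject positive if any informative SNP's mean ratio passes
#' [classify_ase()]. Subjects heterozygous at no marker are
#' `uninformative`. When a subject's informative SNPs disagree in direction
#' (one at or above the upper threshold and another at or below the lower),
#' the call is still positive but flagged discordant.
#'
#' @param peaks peak-area data.frame as from [simulate_peaks()] /
#'   [read_peaks()] (`area_allele0`/`area_allele1` coded by allele).
#' @param genotypes subjects x SNPs dosage matrix (all cohort subjects).
#' @param marker_snp_ids the transcribed marker SNPs.
#' @param lower,upper,inclusive thresholds passed to [classify_ase()].
#' @param expected_replicates replicate count expected per SNP (default
#'   `2 preps x 2 duplicates = 4`).
#' @return object of class `ase_calls`: list with `calls` (data.frame
#'   `subject_id`, `call`, `concordant`, `n_informative`,
#'   `informative_snps`) and `per_snp` (data.frame `subject_id`, `snp_id`,
#'   `mean_ratio`, `n_ratios`, `snp_call`).
#' @export
call_cohort <- function(peaks, genotypes, marker_snp_ids,
                        lower = 0.67, upper = 1.5, inclusive = TRUE,
                        expected_replicates = 4L) {
  stopifnot(is.matrix(genotypes))
  peaks <- peaks[peaks$snp_id %in% marker_snp_ids, , drop = FALSE]

  ## QC: peak rows must reference heterozygous subject-marker pairs
  g_at <- genotypes[cbind(match(peaks$subject_id, rownames(genotypes)),
                          match(peaks$snp_id, colnames(genotypes)))]
  bad <- which(is.na(g_at) | g_at != 1L)
  if (length(bad))
    stop_validation("QC error: peak measurements for non-heterozygous subject-SNP pairs (rows %s)",
                    paste(utils::head(bad, 10), collapse = ", "))

  common <- vapply(marker_snp_ids, function(s) common_allele(genotypes[, s]), "")
  per_snp <- list()
  key <- paste(peaks$subject_id, peaks$snp_id, sep = "\r")
  for (k in unique(key)) {
    rows <- peaks[key == k, , drop = FALSE]
    s <- rows$snp_id[1]
    ## orient areas to common/rare
    if (common[[s]] == "0") {
      com <- rows$area_allele0; rar <- rows$area_allele1
    } else {
      com <- rows$area_allele1; rar <- rows$area_allele0
    }
    ratio <- com / rar
    is_g <- rows$template == "gDNA"
    if (!any(is_g))
      stop_validation("pairing error: no gDNA measurement for subject %s SNP %s",
                      rows$subject_id[1], s)
    g_slot <- paste(rows$prep[is_g], rows$duplicate[is_g])
    g_ratio <- ratio[is_g]
    c_slot <- paste(rows$prep[!is_g], rows$duplicate[!is_g])
    m <- match(c_slot, g_slot)
    norm <- ratio[!is_g] / ifelse(is.na(m), mean(g_ratio), g_ratio[m])
    rm_res <- withCallingHandlers(
      replicate_mean(norm, expected_n = expected_replicates),
      warning = function(w) invokeRestart("muffleWarning"))
    per_snp[[length(per_snp) + 1L]] <- data.frame(
      subject_id = rows$subject_id[1], snp_id = s,
      mean_ratio = rm_res$mean_ratio, n_ratios = rm_res$n_ratios,
      stringsAsFactors = FALSE)
  }
  per_snp <- if (length(per_snp)) do.call(rbind, per_snp) else
    data.frame(subject_id = character(), snp_id = character(),
               mean_ratio = numeric(), n_ratios = integer())
  per_snp$snp_call <- if (nrow(per_snp))
    vapply(per_snp$mean_ratio, classify_ase, "", lower = lower,
           upper = upper, inclusive = inclusive) else character()

  subjects <- rownames(genotypes)
  calls <- data.frame(subject_id = subjects, call = "uninformative",
                      concordant = NA, n_informative = 0L,
                      informative_snps = "", stringsAsFactors = FALSE)
  for (i in seq_along(subjects)) {
    mine <- per_snp[per_snp$subject_id == subjects[i], , drop = FALSE]
    if (nrow(mine) == 0) next
    pos <- mine$snp_call == "positive"
    up <- mine$mean_ratio >= upper
    dn <- mine$mean_ratio <= lower
    calls$call[i] <- if (any(pos)) "positive" else "negative"
    calls$concordant[i] <- !(any(up) && any(dn))
    calls$n_informative[i] <- nrow(mine)
    calls$informative_snps[i] <- paste(mine$snp_id, collapse = ",")
  }
  structure(list(calls = calls, per_snp = per_snp,
                 thresholds = c(lower = lower, upper = upper),
                 inclusive = inclusive),
            class = "ase_calls")
}

#' @export
print.ase_calls <- function(x, ...) {
  tab <- table(factor(x$calls$call, c("positive", "negative", "uninformative")))
  n <- nrow(x$calls)
  cat(sprintf("ASE calls for %d subjects: %d positive (%.1f%%), %d negative, %d uninformative\n",
              n, tab[["positive"]], 100 * tab[["positive"]] / n,
              tab[["negative"]], tab[["uninformative"]]))
  invisible(x)
}

#' Cohort summary stratified by clinical covariates
#'
#' Cross-tabulates ASE-positive vs ASE-negative subjects (negative here
#' meaning everyone not called positive, i.e. the remainder of the cohort)
#' against each clinical covariate, reports percentages of the whole cohort
#' at 1 decimal, and runs Fisher exact tests for the configured clinical
#' 2x2 contrasts.
#'
#' @param calls an `ase_calls` object (or its `calls` data.frame).
#' @param covariates data.frame with `subject_id` and covariate columns.
#' @param covariate_names covariates to tabulate (defaults to the clinical
#'   set present).
#' @param contrasts named list; each element
#'   `list(covariate =, level_a =, level_b =)` builds a 2x2 of phenotype
#'   group against `level_a` vs `level_b` (`level_b = NULL` means all other
#'   non-missing levels).
#' @return object of class `cohort_summary`: list with `n`, `n_positive`,
#'   `prevalence_percent`, `counts` (long data.frame), `strata_prevalence`,
#'   and `fisher` (contrast, p).
#' @export
summarize_cohort <- function(calls, covariates,
                             covariate_names = intersect(
                               c("sex", "location", "ethnicity", "stage",
                                 "family_history"), names(covariates)),
                             contrasts = default_clinical_contrasts()) {
  cl <- if (inherits(calls, "ase_calls")) calls$calls else calls
  missing <- setdiff(cl$subject_id, covariates$subject_id)
  if (length(missing))
    stop_validation("covariates missing for subjects: %s",
                    paste(utils::head(missing, 5), collapse = ", "))
  cov <- covariates[match(cl$subject_id, covariates$subject_id), , drop = FALSE]
  pos <- cl$call == "positive"
  n <- nrow(cl)

  counts <- do.call(rbind, lapply(covariate_names, function(v) {
    x <- cov[[v]]
    if (anyNA(x)) {
      warning(sprintf("unknown %s for %d subject(s): placed in 'Unknown' stratum",
                      v, sum(is.na(x))), call. = FALSE)
      x[is.na(x)] <- "Unknown"
    }
    lev <- unique(x)
    data.frame(covariate = v, level = lev,
               n_total = vapply(lev, function(l) sum(x == l), 0L),
               n_ase_pos = vapply(lev, function(l) sum(x == l & pos), 0L),
               n_ase_neg = vapply(lev, function(l) sum(x == l & !pos), 0L),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  counts$pct_total <- round_half_up(100 * counts$n_total / n, 1)
  counts$pct_ase_pos <- round_half_up(100 * counts$n_ase_pos / n, 1)
  counts$pct_ase_neg <- round_half_up(100 * counts$n_ase_neg / n, 1)
  ## within-stratum prevalence (share of a stratum that is ASE positive)
  strata <- counts[c("covariate", "level", "n_total", "n_ase_pos")]
  strata$prevalence_percent <- ifelse(strata$n_total > 0,
    round_half_up(100 * strata$n_ase_pos / strata$n_total, 1), 0)

  fisher <- data.frame(contrast = character(), a = integer(), b = integer(),
                       c = integer(), d = integer(), p = numeric(),
                       stringsAsFactors = FALSE)
  for (nm in names(contrasts)) {
    ct <- contrasts[[nm]]
    x <- cov[[ct$covariate]]
    in_a <- !is.na(x) & x %in% ct$level_a
    in_b <- if (is.null(ct$level_b)) !is.na(x) & !in_a
            else !is.na(x) & x %in% ct$level_b
    tab <- matrix(c(sum(pos & in_a), sum(pos & in_b),
                    sum(!pos & in_a), sum(!pos & in_b)),
                  nrow = 2, byrow = TRUE)
    p <- tryCatch(fisher_exact(tab), error = function(e) NA_real_)
    fisher <- rbind(fisher, data.frame(contrast = nm, a = tab[1, 1], b = tab[1, 2],
                                       c = tab[2, 1], d = tab[2, 2], p = p,
                                       stringsAsFactors = FALSE))
  }
  structure(list(n = n, n_positive = sum(pos),
                 prevalence_percent = round_half_up(100 * sum(pos) / n, 1),
                 counts = counts, strata_prevalence = strata, fisher = fisher),
            class = "cohort_summary")
}

#' Default clinical 2x2 contrasts for the cohort summary
#'
#' Colon vs rectum primaries, and stage IV vs all other stages, each by ASE
#' status.
#' @return named list of contrast definitions.
#' @export
default_clinical_contrasts <- function() {
  list(colon_vs_rectum = list(covariate = "location",
                              level_a = "Colon", level_b = "Rectum"),
       stage_iv_vs_other = list(covariate = "stage",
                                level_a = "IV", level_b = NULL))
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("cohort of %d subjects; %d ASE positive (%.1f%%)\n",
              x$n, x$n_positive, x$prevalence_percent))
  for (i in seq_len(nrow(x$fisher)))
    cat(sprintf("  %s: p = %.3f (Fisher exact)\n",
                x$fisher$contrast[i], x$fisher$p[i]))
  invisible(x)
}

#' Carrier summary for one SNP by ASE status
#'
#' Dominant (carrier) coding: a subject counts once if carrying at least
#' one copy of allele 1 at the SNP.
#'
#' @param genotypes subjects x SNPs dosage matrix.
#' @param calls `ase_calls` object or its `calls` data.frame.
#' @param snp_id SNP to summarize.
#' @return data.frame with one row per group (`ASE+`, `rest`): `n`,
#'   `n_carriers`, `percent` (1 dp).
#' @export
carrier_summary <- function(genotypes, calls, snp_id) {
  if (!snp_id %in% colnames(genotypes))
    stop_validation("SNP '%s' absent from genotypes", snp_id)
  cl <- if (inherits(calls, "ase_calls")) calls$calls else calls
  g <- genotypes[match(cl$subject_id, rownames(genotypes)), snp_id]
  pos <- cl$call == "positive"
  one <- function(sel) {
    gg <- g[sel]
    n <- sum(!is.na(gg))
    k <- sum(gg >= 1, na.rm = TRUE)
    c(n = n, n_carriers = k,
      percent = if (n > 0) round_half_up(100 * k / n, 1) else 0)
  }
  out <- rbind(`ASE+` = one(pos), rest = one(!pos))
  data.frame(group = rownames(out), out, row.names = NULL,
             stringsAsFactors = FALSE)
}
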