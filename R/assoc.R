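#' Allelic 2x2 contingency table for one SNP
#'
#' Counts two alleles per subject (allelic coding), split by phenotype
#' group. Rows are groups (ASE-positive, remainder), columns are allele 2
#' (the coded alternate allele) and allele 1. Subjects with a missing
#' genotype are dropped for this SNP only. Carrier (dominant) coding —
#' one count per subject, carrier vs non-carrier — is available via
#' `coding = "carrier"`.
#'
#' @param genotypes_for_snp numeric vector of 0/1/2 dosages (NA allowed).
#' @param phenotype_labels logical (TRUE = ASE positive) or character
#'   vector with `"positive"` marking cases, aligned with the genotypes.
#' @param coding `"allelic"` (default) or `"carrier"`.
#' @return 2x2 integer matrix with dimnames
#'   `list(c("ASE+", "rest"), c("allele2", "allele1"))` (or carrier
#'   columns).
#' @export
allele_table <- function(genotypes_for_snp, phenotype_labels,
                         coding = c("allelic", "carrier")) {
  coding <- match.arg(coding)
  pos <- if (is.logical(phenotype_labels)) phenotype_labels
         else phenotype_labels == "positive"
  keep <- !is.na(genotypes_for_snp) & !is.na(pos)
  g <- genotypes_for_snp[keep]; pos <- pos[keep]
  if (length(g) == 0) stop_validation("all genotypes missing for this SNP")
  if (!any(pos) || all(pos))
    stop_validation("degenerate table: a phenotype group has no subjects")
  if (coding == "allelic") {
    tab <- matrix(c(sum(g[pos]), 2 * sum(pos) - sum(g[pos]),
                    sum(g[!pos]), 2 * sum(!pos) - sum(g[!pos])),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("ASE+", "rest"), c("allele2", "allele1")))
  } else {
    tab <- matrix(c(sum(g[pos] >= 1), sum(pos) - sum(g[pos] >= 1),
                    sum(g[!pos] >= 1), sum(!pos) - sum(g[!pos] >= 1)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("ASE+", "rest"), c("carrier", "non-carrier")))
  }
  storage.mode(tab) <- "integer"
  tab
}

check_table2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) || any(table != floor(table)))
    stop_validation("expected a 2x2 table of non-negative integer counts")
  if (sum(table) == 0) stop_validation("empty contingency table")
  table
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson statistic without continuity correction, 1 degree of freedom,
#' computed by the closed form `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`,
#' with the p-value from the upper chi-square tail.
#'
#' @param table 2x2 matrix of counts `rbind(c(a, b), c(c, d))`.
#' @return list with `chi2` and `p`.
#' @export
pearson_chi2 <- function(table) {
  table <- check_table2x2(table)
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0))
    stop_computation("undefined test: a zero row or column margin")
  N <- sum(table)
  chi2 <- N * (a * d - b * c)^2 / prod(margins)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Odds ratio of a 2x2 table
#'
#' Cross-product ratio `(a d)/(b c)`. By default any zero cell makes the
#' estimate undefined and `NA` is returned (rendered as the literal
#' `"n/a"` in reports); `haldane = TRUE` instead adds 0.5 to every cell
#' (Haldane-Anscombe correction).
#'
#' @param table 2x2 count matrix.
#' @param haldane apply the +0.5 correction instead of returning `NA`.
#' @return positive numeric, or `NA_real_` when undefined.
#' @export
odds_ratio_from_table <- function(table, haldane = FALSE) {
  table <- check_table2x2(table)
  if (any(table == 0)) {
    if (!haldane) return(NA_real_)
    table <- table + 0.5
  }
  (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
}

#' Odds ratio from two group frequencies
#'
#' `(f1/(1-f1)) / (f2/(1-f2))` — the allelic odds ratio implied by the
#' allele frequencies of the two groups (useful for reproducing published
#' odds ratios from reported frequencies).
#'
#' @param f1,f2 frequencies strictly inside (0, 1).
#' @return positive numeric; `NA_real_` if either frequency is on the
#'   boundary.
#' @export
odds_ratio_from_freqs <- function(f1, f2) {
  if (any(!is.finite(c(f1, f2))) || f1 <= 0 || f1 >= 1 || f2 <= 0 || f2 >= 1)
    return(NA_real_)
  (f1 / (1 - f1)) / (f2 / (1 - f2))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact enumeration over the hypergeometric support with fixed margins;
#' the two-sided p-value follows the probability-mass rule: the sum of the
#' probabilities of all tables no more probable than the observed one
#' (relative tolerance 1e-9 on the comparison). A table with a zero margin
#' has a single support point and p = 1.
#'
#' @param table 2x2 count matrix.
#' @param max_total enumeration guard; totals above it raise an error
#'   advising the chi-square test (default 1e6).
#' @return two-sided p-value in (0, 1].
#' @export
fisher_exact <- function(table, max_total = 1e6) {
  table <- check_table2x2(table)
  if (sum(table) > max_total)
    stop_validation("table total %d exceeds the enumeration bound; use pearson_chi2()",
                    sum(table))
  m1 <- table[1, 1] + table[1, 2]   # row 1 total
  m2 <- table[2, 1] + table[2, 2]
  kk <- table[1, 1] + table[2, 1]   # column 1 total
  support <- max(0, kk - m2):min(kk, m1)
  probs <- stats::dhyper(support, m1, m2, kk)
  p_obs <- stats::dhyper(table[1, 1], m1, m2, kk)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

#' Allelic association scan across SNPs
#'
#' For each SNP: allelic 2x2 table of ASE-positive subjects against the
#' remainder of the cohort, allele-2 frequencies per group, Pearson
#' chi-square (no continuity correction), and the odds ratio (NA when a
#' zero cell makes it undefined). Per-SNP failures (monomorphic SNP, empty
#' margin) are recorded in the row and the scan continues.
#'
#' @param genotypes subjects x SNPs 0/1/2 dosage matrix.
#' @param phenotype_labels logical or `"positive"`-coded character vector
#'   aligned with `rownames(genotypes)`, or an `ase_calls` object.
#' @param snp_ids SNPs to scan (default: all columns).
#' @param drop_uninformative when `phenotype_labels` is an `ase_calls`
#'   object, drop subjects called `uninformative` instead of counting them
#'   in the remainder group (default FALSE: the remainder is the whole
#'   rest of the cohort).
#' @param coding passed to [allele_table()].
#' @return data.frame of class `assoc_scan`: `snp_id`, `n_subjects_used`,
#'   `freq2_ase`, `freq2_rest`, `chi2`, `p`, `odds_ratio`, `note`.
#' @export
assoc_scan <- function(genotypes, phenotype_labels, snp_ids = colnames(genotypes),
                       drop_uninformative = FALSE,
                       coding = c("allelic", "carrier")) {
  coding <- match.arg(coding)
  if (inherits(phenotype_labels, "ase_calls")) {
    cl <- phenotype_labels$calls
    cl <- cl[match(rownames(genotypes), cl$subject_id), ]
    pos <- cl$call == "positive"
    if (drop_uninformative) pos[cl$call == "uninformative"] <- NA
  } else if (is.logical(phenotype_labels)) {
    pos <- phenotype_labels
  } else {
    pos <- phenotype_labels == "positive"
  }
  if (sum(pos, na.rm = TRUE) == 0 || sum(!pos, na.rm = TRUE) == 0)
    stop_validation("degenerate phenotype: need subjects in both groups")
  rows <- lapply(snp_ids, function(s) {
    out <- data.frame(snp_id = s, n_subjects_used = NA_integer_,
                      freq2_ase = NA_real_, freq2_rest = NA_real_,
                      chi2 = NA_real_, p = NA_real_, odds_ratio = NA_real_,
                      note = "", stringsAsFactors = FALSE)
    tryCatch({
      tab <- allele_table(genotypes[, s], pos, coding = coding)
      out$n_subjects_used <- as.integer(sum(tab) /
                                          if (coding == "allelic") 2L else 1L)
      out$freq2_ase <- tab[1, 1] / sum(tab[1, ])
      out$freq2_rest <- tab[2, 1] / sum(tab[2, ])
      ct <- tryCatch(pearson_chi2(tab), error = function(e) {
        out$note <<- conditionMessage(e); NULL
      })
      if (!is.null(ct)) { out$chi2 <- ct$chi2; out$p <- ct$p }
      out$odds_ratio <- odds_ratio_from_table(tab)
      out
    }, error = function(e) { out$note <- conditionMessage(e); out })
  })
  res <- do.call(rbind, rows)
  class(res) <- c("assoc_scan", class(res))
  res
}

#' Format an association scan like a published table
#'
#' Frequencies at 2 decimals, odds ratios at 1 decimal with `"n/a"` for
#' undefined estimates, p-values in scientific notation below 1e-3.
#'
#' @param scan an `assoc_scan` data.frame.
#' @return character-formatted data.frame.
#' @export
format_assoc <- function(scan) {
  data.frame(SNP = scan$snp_id,
             freq2_ASE = sprintf("%.2f", scan$freq2_ase),
             freq2_rest = sprintf("%.2f", scan$freq2_rest),
             P = ifelse(is.na(scan$p), "n/a",
                        ifelse(scan$p < 1e-3, sprintf("%.1e", scan$p),
                               sprintf("%.2f", scan$p))),
             OR = ifelse(is.na(scan$odds_ratio), "n/a",
                         sprintf("%.1f", round_half_up(scan$odds_ratio, 1))),
             stringsAsFactors = FALSE)
}
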