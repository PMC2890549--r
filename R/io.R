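#' Write a phased cohort as a minimal VCF
#'
#' GT-only VCF dialect: columns CHROM, POS (1-based, sequential per SNP),
#' ID, REF, ALT, QUAL, FILTER, INFO, FORMAT, then one column per subject.
#' Phased genotypes use `|`, unphased `/`.
#'
#' @param cohort a `phased_cohort`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_genotypes_vcf <- function(cohort, path) {
  sep <- if (isTRUE(cohort$phase_known)) "|" else "/"
  gt <- matrix(paste(t(cohort$hap_a), t(cohort$hap_b), sep = sep),
               nrow = length(cohort$snp_ids))  # SNPs x subjects
  header <- c("##fileformat=VCFv4.2",
              "##source=aseassoc",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", cohort$subject_id), collapse = "\t"))
  body <- paste("1", seq_along(cohort$snp_ids) * 1000L, cohort$snp_ids,
                "A", "G", ".", ".", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a genotype dosage matrix as TSV
#'
#' Rows are subjects, columns SNP ids, cells 0/1/2 (allele-1 dosage) or NA.
#'
#' @param genotypes subjects x SNPs matrix with dimnames.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  df <- data.frame(subject_id = rownames(genotypes), genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix from VCF or TSV
#'
#' Accepts either the minimal GT-only VCF dialect written by
#' [write_genotypes_vcf()] (parsed with \pkg{vcfR}) or a TSV dosage matrix
#' with a `subject_id` column. Returns the subjects x SNPs 0/1/2 matrix with
#' per-SNP phase flags and, for VCF input, the 1-based positions as
#' attributes.
#'
#' @param path input path; format detected from the first line (`##`) or a
#'   `.vcf` extension.
#' @return integer matrix (subjects x SNPs, NA for missing) with attributes
#'   `phased` (logical, TRUE when every non-missing GT used `|`) and, for
#'   VCF, `pos` (named integer vector).
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop_validation("genotype file '%s' does not exist", path)
  first <- readLines(path, n = 1)
  if (startsWith(first, "##") || grepl("\\.vcf$", path)) {
    read_genotypes_vcf(path)
  } else {
    read_genotypes_tsv(path)
  }
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")           # SNPs x subjects
  ids <- vcfR::getID(v)
  if (anyDuplicated(colnames(gt)))
    stop_validation("VCF '%s': duplicate subject ids", path)
  ok <- is.na(gt) | grepl("^[01.]([|/][01.])?$", gt)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop_validation("VCF '%s': malformed GT '%s' at record %d",
                    path, gt[bad[1], bad[2]], bad[1])
  }
  dose <- function(x) {
    a <- substr(x, 1, 1); b <- substr(x, 3, 3)
    ifelse(is.na(x) | a == "." | b == ".", NA_integer_,
           as.integer(a) + as.integer(b))
  }
  m <- t(apply(gt, 1, dose))
  dimnames(m) <- list(ids, colnames(gt))
  m <- t(m)                                            # subjects x SNPs
  phased <- all(grepl("\\|", gt[!is.na(gt)]))
  structure(m, phased = phased,
            pos = stats::setNames(as.integer(vcfR::getPOS(v)), ids))
}

read_genotypes_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  if (!"subject_id" %in% names(df))
    stop_validation("genotype TSV '%s': missing 'subject_id' column", path)
  if (anyDuplicated(df$subject_id))
    stop_validation("genotype TSV '%s': duplicate subject ids", path)
  m <- as.matrix(df[setdiff(names(df), "subject_id")])
  if (!all(m %in% c(0, 1, 2, NA)))
    stop_validation("genotype TSV '%s': cells must be 0/1/2/NA", path)
  storage.mode(m) <- "integer"
  rownames(m) <- df$subject_id
  structure(m, phased = FALSE)
}

#' Read an allelic peak-area table
#'
#' CSV with columns `subject_id`, `snp_id`, `template` (gDNA/cDNA), `prep`,
#' `duplicate`, `area_allele0`, `area_allele1`.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stop_validation("peaks file '%s' does not exist", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "snp_id", "template", "prep", "duplicate",
              "area_allele0", "area_allele1")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop_validation("peaks file '%s': missing columns %s", path,
                    paste(missing, collapse = ", "))
  if (!all(df$template %in% c("gDNA", "cDNA")))
    stop_validation("peaks file '%s': template must be 'gDNA' or 'cDNA'", path)
  if (any(df$area_allele0 <= 0 | df$area_allele1 <= 0))
    stop_validation("peaks file '%s': peak areas must be strictly positive", path)
  df
}

#' Read a clinical covariate table
#' @param path CSV path with a `subject_id` column.
#' @return data.frame.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop_validation("covariates file '%s' does not exist", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df))
    stop_validation("covariates file '%s': missing 'subject_id' column", path)
  df
}
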