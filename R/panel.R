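#' Haplotype panel
#'
#' A pool of phased haplotypes with population frequencies, standing in for a
#' reference panel (e.g. a HapMap-style background) from which diploid
#' subjects are drawn under Hardy-Weinberg (random union of gametes). All
#' linkage disequilibrium in a simulated cohort arises from this pool; there
#' is no recombination model.
#'
#' @param snp_ids character vector of M SNP identifiers (ordered).
#' @param haplotypes numeric/integer matrix, one row per haplotype, M columns,
#'   entries in \{0, 1\} (1 = alternate allele).
#' @param frequencies non-negative haplotype frequencies, one per row,
#'   summing to 1 (tolerance 1e-9).
#' @return an object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(snp_ids, haplotypes, frequencies) {
  haplotypes <- as.matrix(haplotypes)
  if (length(snp_ids) != ncol(haplotypes))
    stop_validation("panel field 'haplotypes': expected %d columns (one per SNP), got %d",
                    length(snp_ids), ncol(haplotypes))
  if (nrow(haplotypes) < 2)
    stop_validation("panel field 'haplotypes': at least 2 haplotypes required")
  if (!all(haplotypes %in% c(0, 1)))
    stop_validation("panel field 'haplotypes': alleles must be 0 or 1")
  if (length(frequencies) != nrow(haplotypes))
    stop_validation("panel field 'frequencies': need one frequency per haplotype")
  if (any(frequencies < 0) || abs(sum(frequencies) - 1) > 1e-9)
    stop_validation("panel field 'frequencies': must be non-negative and sum to 1")
  colnames(haplotypes) <- snp_ids
  structure(list(snp_ids = as.character(snp_ids),
                 haplotypes = haplotypes,
                 frequencies = as.numeric(frequencies)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes x %d SNPs\n",
              nrow(x$haplotypes), length(x$snp_ids)))
  cat("allele-1 frequencies:\n")
  print(round(panel_allele_freqs(x), 3))
  invisible(x)
}

#' Population allele-1 frequency of every SNP in a panel
#' @param panel a [haplotype_panel()].
#' @return named numeric vector.
#' @export
panel_allele_freqs <- function(panel) {
  drop(panel$frequencies %*% panel$haplotypes)
}

#' Build the default synthetic haplotype panel
#'
#' Constructs a panel of `n_haplotypes` equifrequent haplotypes over the
#' configured locus and marker SNPs. Allele-1 carriers for each SNP are an
#' independent random subset of haplotypes of size `round(freq * H)`, which
#' places unrelated SNPs near linkage equilibrium while keeping realized
#' allele frequencies within 1/(2H) of their targets. The causal SNP's
#' carrier set is copied verbatim onto the proxy SNP, planting an r² = 1
#' proxy whose recovery the association scan can be tested against.
#'
#' @param config a [sim_config()].
#' @return a [haplotype_panel()].
#' @export
build_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "panel"))
  snp_ids <- c(config$locus_snp_ids, config$marker_snp_ids)
  M <- length(snp_ids)
  H <- config$n_haplotypes
  hap <- matrix(0L, nrow = H, ncol = M, dimnames = list(NULL, snp_ids))

  ## per-SNP target allele-1 frequencies
  freqs <- stats::setNames(numeric(M), snp_ids)
  freqs[config$locus_snp_ids] <- sample(seq(0.05, 0.50, by = 0.05),
                                        length(config$locus_snp_ids), replace = TRUE)
  freqs[config$marker_snp_ids] <- config$marker_freq
  freqs[config$causal_snp_id] <- config$causal_freq

  for (s in snp_ids) {
    if (s == config$proxy_snp_id) next
    carriers <- sample.int(H, max(1L, round(freqs[[s]] * H)))
    hap[carriers, s] <- 1L
  }
  if (!is.na(config$proxy_snp_id))
    hap[, config$proxy_snp_id] <- hap[, config$causal_snp_id]

  haplotype_panel(snp_ids, hap, rep(1 / H, H))
}
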