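#' Greedy tag-SNP selection with two-tag haplotype rescue
#'
#' Selects tag SNPs so that every common SNP (minor-allele frequency at or
#' above `maf_threshold`) is covered at pairwise `r2 > r2_threshold` by
#' some tag. The greedy step repeatedly picks the SNP covering the most
#' still-uncovered common SNPs (ties broken by higher MAF, then input
#' order). When the only remaining coverage is self-coverage, each
#' uncovered SNP is first offered rescue by the best haplotype of two
#' already-selected tags ([two_tag_haplotype_r2()]); only SNPs that rescue
#' fails are promoted to tags of their own.
#'
#' An exhaustive minimal-cover search (all tag subsets of increasing size)
#' is available for panels of at most 15 common SNPs.
#'
#' @param genotypes subjects x SNPs 0/1/2 dosage matrix.
#' @param r2_threshold coverage threshold (default 0.8, strict `>`).
#' @param maf_threshold common-SNP cutoff (default 0.05).
#' @param rescue attempt two-tag haplotype rescue (default TRUE).
#' @param exhaustive use exhaustive minimal pairwise cover instead of
#'   greedy (<= 15 common SNPs).
#' @param phased optional `phased_cohort` used for three-locus haplotype
#'   counting during rescue (EM on `genotypes` otherwise).
#' @return object of class `tag_set`: `tags`, `proxy_map` (data.frame
#'   `target`, `proxy`, `proxy_type` self/single/two_tag/uncovered,
#'   `haplotype`, `r2`), `mean_r2`, `n_common`, `n_covered_at_threshold`,
#'   `maf`, plus the thresholds used.
#' @export
greedy_tag <- function(genotypes, r2_threshold = 0.8, maf_threshold = 0.05,
                       rescue = TRUE, exhaustive = FALSE, phased = NULL) {
  snps <- colnames(genotypes)
  f <- colMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  common <- snps[!is.na(maf[snps]) & maf[snps] >= maf_threshold]
  if (length(common) == 0) {
    warning("no SNPs at or above the MAF threshold; empty tag set", call. = FALSE)
    return(structure(list(tags = character(0),
                          proxy_map = data.frame(target = character(),
                                                 proxy = character(),
                                                 proxy_type = character(),
                                                 haplotype = character(),
                                                 r2 = numeric()),
                          mean_r2 = NA_real_, n_common = 0L,
                          n_covered_at_threshold = 0L, maf = maf,
                          r2_threshold = r2_threshold,
                          maf_threshold = maf_threshold),
                     class = "tag_set"))
  }
  k <- length(common)
  r2 <- matrix(1, k, k, dimnames = list(common, common))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    pl <- pair_ld(genotypes[, common[i]], genotypes[, common[j]])
    r2[i, j] <- r2[j, i] <- if (isTRUE(pl$r2_defined)) pl$r2 else 0
  }
  cover <- r2 > r2_threshold
  diag(cover) <- TRUE

  rescue_entries <- list()
  if (exhaustive) {
    if (k > 15) stop_validation("exhaustive search limited to 15 common SNPs (got %d)", k)
    tags <- NULL
    for (size in seq_len(k)) {
      sets <- utils::combn(k, size, simplify = FALSE)
      for (s in sets) {
        if (all(colSums(cover[s, , drop = FALSE]) > 0)) { tags <- common[s]; break }
      }
      if (!is.null(tags)) break
    }
  } else {
    tags <- character(0)
    covered <- stats::setNames(rep(FALSE, k), common)
    repeat {
      unc <- common[!covered]
      if (length(unc) == 0) break
      ## for each candidate SNP, how many still-uncovered SNPs it covers
      cnt <- rowSums(cover[, unc, drop = FALSE])
      ord <- order(-cnt, -maf[common], seq_len(k))
      best <- ord[1]
      if (cnt[best] >= 2) {
        tags <- c(tags, common[best])
        covered <- covered | cover[best, ]
        next
      }
      ## only single-SNP coverage remains: try two-tag rescue, then self-tag
      for (u in unc) {
        done <- FALSE
        if (rescue && length(tags) >= 2) {
          prs <- utils::combn(tags, 2, simplify = FALSE)
          best_r <- list(r2 = -Inf, haplotype = NA_character_, pair = NULL)
          for (pr in prs) {
            tt <- two_tag_haplotype_r2(u, pr, if (!is.null(phased)) phased else genotypes)
            if (!is.na(tt$r2) && tt$r2 > best_r$r2)
              best_r <- list(r2 = tt$r2, haplotype = tt$haplotype, pair = pr)
          }
          if (is.finite(best_r$r2) && best_r$r2 > r2_threshold) {
            rescue_entries[[u]] <- data.frame(
              target = u, proxy = paste(best_r$pair, collapse = "+"),
              proxy_type = "two_tag", haplotype = best_r$haplotype,
              r2 = best_r$r2, stringsAsFactors = FALSE)
            covered[u] <- TRUE
            done <- TRUE
          }
        }
        if (!done) {
          tags <- c(tags, u)
          covered <- covered | cover[match(u, common), ]
        }
      }
      break
    }
  }

  ## proxy map: every common SNP's best proxy among the selected tags
  pm <- lapply(common, function(target) {
    if (target %in% tags)
      return(data.frame(target = target, proxy = target, proxy_type = "self",
                        haplotype = NA_character_, r2 = 1,
                        stringsAsFactors = FALSE))
    if (!is.null(rescue_entries[[target]]))
      return(rescue_entries[[target]])
    bt <- tags[which.max(r2[target, tags])]
    data.frame(target = target, proxy = bt,
               proxy_type = if (r2[target, bt] > r2_threshold) "single" else "uncovered",
               haplotype = NA_character_, r2 = r2[target, bt],
               stringsAsFactors = FALSE)
  })
  proxy_map <- do.call(rbind, pm)
  structure(list(tags = tags, proxy_map = proxy_map,
                 mean_r2 = mean(proxy_map$r2),
                 n_common = length(common),
                 n_covered_at_threshold = sum(proxy_map$r2 > r2_threshold |
                                                proxy_map$proxy_type == "self"),
                 maf = maf, r2_threshold = r2_threshold,
                 maf_threshold = maf_threshold),
            class = "tag_set")
}

#' @export
print.tag_set <- function(x, ...) {
  cat(sprintf("tag_set: %d tags covering %d/%d common SNPs at r2 > %.2f (mean r2 = %.3f)\n",
              length(x$tags), x$n_covered_at_threshold, x$n_common,
              x$r2_threshold, x$mean_r2))
  invisible(x)
}

#' Coverage summary of a tag set
#'
#' Mean best-proxy r-squared over all common SNPs (tags contribute 1),
#' count covered at the threshold, and the proxy table sorted by r-squared
#' (descending).
#'
#' @param tagset a `tag_set` from [greedy_tag()].
#' @return list with `mean_r2`, `n_common`, `n_tags`,
#'   `n_covered_at_threshold`, and `table` (sorted proxy map).
#' @export
coverage_report <- function(tagset) {
  stopifnot(inherits(tagset, "tag_set"))
  pm <- tagset$proxy_map
  list(mean_r2 = if (nrow(pm)) mean(pm$r2) else NA_real_,
       n_common = tagset$n_common,
       n_tags = length(tagset$tags),
       n_covered_at_threshold = tagset$n_covered_at_threshold,
       table = pm[order(-pm$r2), , drop = FALSE])
}
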