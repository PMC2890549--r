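#' Two-locus haplotype frequencies by EM
#'
#' Maximum-likelihood estimation of the four two-locus haplotype
#' frequencies (p11, p10, p01, p00; indices are allele-1 indicators at each
#' locus) from unphased 0/1/2 dosages. Only double heterozygotes are
#' phase-ambiguous; their expected split between the coupling (1-1 / 0-0)
#' and repulsion (1-0 / 0-1) gamete pairs is updated each iteration.
#' Initialization is at the linkage-equilibrium product of allele
#' frequencies; iteration stops when the largest frequency change drops
#' below `tol` or after `max_iter` iterations. Subjects missing either
#' genotype are dropped (pairwise-complete analysis).
#'
#' @param genotypes_a,genotypes_b numeric vectors of 0/1/2 dosages (NA
#'   allowed), same length.
#' @param tol convergence tolerance on haplotype frequencies (default 1e-10).
#' @param max_iter maximum EM iterations (default 1000).
#' @return object of class `pair_ld` with `hap_freqs` (named p11, p10, p01,
#'   p00), `allele_freqs` (pA, pB), `n_subjects`, `em_iterations`,
#'   `converged`, and a `loglik_trace` attribute (observed-data
#'   log-likelihood per iteration). LD statistics are filled by
#'   [ld_stats()].
#' @export
em_haplotype_freqs <- function(genotypes_a, genotypes_b,
                               tol = 1e-10, max_iter = 1000L) {
  if (length(genotypes_a) != length(genotypes_b))
    stop_validation("genotype vectors must have equal length")
  keep <- !is.na(genotypes_a) & !is.na(genotypes_b)
  ga <- genotypes_a[keep]; gb <- genotypes_b[keep]
  if (length(ga) < 2)
    stop_validation("insufficient data: fewer than 2 subjects with both genotypes")
  if (!all(ga %in% 0:2) || !all(gb %in% 0:2))
    stop_validation("genotypes must be coded 0/1/2")
  n <- length(ga)
  cnt <- matrix(0, 3, 3)
  for (i in seq_len(n)) cnt[ga[i] + 1, gb[i] + 1] <- cnt[ga[i] + 1, gb[i] + 1] + 1

  pA <- sum(ga) / (2 * n); pB <- sum(gb) / (2 * n)
  p <- c(p11 = pA * pB, p10 = pA * (1 - pB), p01 = (1 - pA) * pB,
         p00 = (1 - pA) * (1 - pB))

  loglik <- function(p) {
    P <- matrix(c(p[["p00"]]^2,            2 * p[["p01"]] * p[["p00"]], p[["p01"]]^2,
                  2 * p[["p10"]] * p[["p00"]],
                  2 * (p[["p11"]] * p[["p00"]] + p[["p10"]] * p[["p01"]]),
                  2 * p[["p11"]] * p[["p01"]],
                  p[["p10"]]^2,            2 * p[["p11"]] * p[["p10"]], p[["p11"]]^2),
                3, 3, byrow = TRUE)
    sum(cnt[cnt > 0] * log(P[cnt > 0]))
  }

  trace <- numeric(0)
  it <- 0L; converged <- FALSE
  repeat {
    it <- it + 1L
    denom <- p[["p11"]] * p[["p00"]] + p[["p10"]] * p[["p01"]]
    w <- if (denom > 0) p[["p11"]] * p[["p00"]] / denom else 0.5
    c11 <- 2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3] + w * cnt[2, 2]
    c10 <- 2 * cnt[3, 1] + cnt[3, 2] + cnt[2, 1] + (1 - w) * cnt[2, 2]
    c01 <- 2 * cnt[1, 3] + cnt[2, 3] + cnt[1, 2] + (1 - w) * cnt[2, 2]
    c00 <- 2 * cnt[1, 1] + cnt[1, 2] + cnt[2, 1] + w * cnt[2, 2]
    p_new <- c(p11 = c11, p10 = c10, p01 = c01, p00 = c00) / (2 * n)
    trace <- c(trace, loglik(p_new))
    delta <- max(abs(p_new - p))
    p <- p_new
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  structure(list(snp_a = NA_character_, snp_b = NA_character_,
                 hap_freqs = p,
                 allele_freqs = c(pA = p[["p11"]] + p[["p10"]],
                                  pB = p[["p11"]] + p[["p01"]]),
                 n_subjects = n, em_iterations = it, converged = converged,
                 D = NA_real_, D_prime = NA_real_, r2 = NA_real_,
                 r2_defined = NA),
            class = "pair_ld", loglik_trace = trace)
}

#' Haplotype frequencies by direct gamete counting on phased data
#'
#' @param hap_a,hap_b 0/1 allele vectors for the two haplotypes of each
#'   subject at locus A and B respectively: `hap_a` and `hap_b` are n x 2
#'   matrices (columns = locus A, locus B).
#' @return named frequency vector (p11, p10, p01, p00).
#' @export
count_haplotype_freqs <- function(hap_a, hap_b) {
  gam <- rbind(hap_a, hap_b)   # 2n gametes x 2 loci
  key <- paste0(gam[, 1], gam[, 2])
  f <- function(k) mean(key == k)
  c(p11 = f("11"), p10 = f("10"), p01 = f("01"), p00 = f("00"))
}

#' Fill D, D' and r-squared from haplotype frequencies
#'
#' Standard definitions: `D = p11 - pA*pB`;
#' `r2 = D^2 / (pA(1-pA) pB(1-pB))`; `D' = D/Dmax` where `Dmax` is
#' `min(pA(1-pB), (1-pA)pB)` for positive D and `min(pA*pB, (1-pA)(1-pB))`
#' for negative D. When either locus is monomorphic r-squared is undefined:
#' the `r2_defined` flag is set to `FALSE` and `r2` to `NA` (never silently
#' 0). r-squared is clipped to [0, 1] against floating-point error.
#'
#' @param pair a `pair_ld` object (or bare named haplotype-frequency
#'   vector).
#' @return the `pair_ld` object with `D`, `D_prime`, `r2`, `r2_defined`
#'   populated.
#' @export
ld_stats <- function(pair) {
  if (!inherits(pair, "pair_ld")) {
    pair <- structure(list(snp_a = NA_character_, snp_b = NA_character_,
                           hap_freqs = pair,
                           allele_freqs = c(pA = pair[["p11"]] + pair[["p10"]],
                                            pB = pair[["p11"]] + pair[["p01"]]),
                           n_subjects = NA_integer_, em_iterations = 0L,
                           converged = TRUE, D = NA_real_, D_prime = NA_real_,
                           r2 = NA_real_, r2_defined = NA),
                      class = "pair_ld")
  }
  p <- pair$hap_freqs
  pA <- p[["p11"]] + p[["p10"]]; pB <- p[["p11"]] + p[["p01"]]
  D <- p[["p11"]] - pA * pB
  pair$D <- D
  eps <- 1e-12
  if (pA < eps || pA > 1 - eps || pB < eps || pB > 1 - eps) {
    pair$r2 <- NA_real_; pair$D_prime <- NA_real_; pair$r2_defined <- FALSE
    return(pair)
  }
  pair$r2_defined <- TRUE
  pair$r2 <- min(max(D^2 / (pA * (1 - pA) * pB * (1 - pB)), 0), 1)
  if (D > 0) {
    pair$D_prime <- D / min(pA * (1 - pB), (1 - pA) * pB)
  } else if (D < 0) {
    pair$D_prime <- D / min(pA * pB, (1 - pA) * (1 - pB))
  } else pair$D_prime <- 0
  pair
}

#' Pairwise LD between two SNPs from unphased genotypes
#'
#' Convenience wrapper: [em_haplotype_freqs()] followed by [ld_stats()].
#'
#' @inheritParams em_haplotype_freqs
#' @param snp_a,snp_b optional SNP names recorded on the result.
#' @return a `pair_ld` object.
#' @export
pair_ld <- function(genotypes_a, genotypes_b, snp_a = NA_character_,
                    snp_b = NA_character_, tol = 1e-10, max_iter = 1000L) {
  out <- ld_stats(em_haplotype_freqs(genotypes_a, genotypes_b,
                                     tol = tol, max_iter = max_iter))
  out$snp_a <- snp_a; out$snp_b <- snp_b
  out
}

#' @export
print.pair_ld <- function(x, ...) {
  cat(sprintf("pair_ld %s-%s: r2 = %s, D = %.4f, D' = %s (EM %d iter, %s)\n",
              x$snp_a, x$snp_b,
              if (isTRUE(x$r2_defined)) sprintf("%.4f", x$r2) else "undefined",
              x$D,
              if (isTRUE(x$r2_defined)) sprintf("%.4f", x$D_prime) else "undefined",
              x$em_iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

## ---- multi-locus EM (used for three-locus two-tag proxies) ----

## Enumerate, for one multi-locus genotype vector, the unordered haplotype
## index pairs consistent with it. Haplotype index = 1 + sum(allele * 2^(pos-1)).
compatible_pairs <- function(g) {
  L <- length(g)
  het <- which(g == 1)
  base <- as.integer(g == 2)
  idx <- function(v) 1L + as.integer(sum(v * 2^(seq_len(L) - 1L)))
  if (length(het) == 0) {
    matrix(rep(idx(base), 2), 1, 2)
  } else {
    ## fix the first het locus on haplotype A to enumerate unordered pairs once
    rest <- het[-1]
    subsets <- if (length(rest) == 0) list(integer(0)) else
      unlist(lapply(0:length(rest), function(k)
        utils::combn(rest, k, simplify = FALSE)), recursive = FALSE)
    t(vapply(subsets, function(s) {
      a <- base; b <- base
      a[c(het[1], s)] <- 1L
      b[setdiff(het, c(het[1], s))] <- 1L
      c(idx(a), idx(b))
    }, integer(2)))
  }
}

#' Multi-locus haplotype frequencies by EM
#'
#' Generalization of [em_haplotype_freqs()] to L loci (intended for L = 3,
#' the two-tag proxy computation): EM over the 2^L haplotypes, enumerating
#' all phase configurations consistent with each multi-locus genotype.
#' Initialization at the product of allele frequencies.
#'
#' @param genotypes n x L matrix of 0/1/2 dosages (rows with any NA are
#'   dropped).
#' @param tol,max_iter as in [em_haplotype_freqs()].
#' @return list with `freqs` (length 2^L, named by allele strings in locus
#'   order, e.g. `"101"`), `em_iterations`, `converged`, `loglik`.
#' @export
em_haplotype_freqs_multi <- function(genotypes, tol = 1e-10, max_iter = 1000L) {
  G <- as.matrix(genotypes)
  G <- G[stats::complete.cases(G), , drop = FALSE]
  n <- nrow(G); L <- ncol(G)
  if (n < 2) stop_validation("insufficient data: fewer than 2 complete subjects")
  H <- 2^L
  hap_names <- apply(expand.grid(rep(list(0:1), L))[, , drop = FALSE], 1,
                     paste, collapse = "")
  ## group identical genotype rows
  key <- apply(G, 1, paste, collapse = "")
  groups <- table(key)
  pats <- do.call(rbind, lapply(strsplit(names(groups), ""), as.integer))
  pairs <- lapply(seq_len(nrow(pats)), function(i) compatible_pairs(pats[i, ]))

  pf <- colSums(G) / (2 * n)
  allele_mat <- expand.grid(rep(list(0:1), L))
  p <- apply(allele_mat, 1, function(a) prod(ifelse(a == 1, pf, 1 - pf)))
  p <- p / sum(p)

  it <- 0L; converged <- FALSE; ll <- NA_real_
  repeat {
    it <- it + 1L
    counts <- numeric(H); ll_new <- 0
    for (gi in seq_along(pairs)) {
      pr <- pairs[[gi]]
      w <- ifelse(pr[, 1] == pr[, 2], p[pr[, 1]]^2, 2 * p[pr[, 1]] * p[pr[, 2]])
      tot <- sum(w)
      if (tot <= 0) { w <- rep(1 / length(w), length(w)); tot <- NA_real_ }
      wn <- w / sum(w) * groups[[gi]]
      for (r in seq_len(nrow(pr))) {
        counts[pr[r, 1]] <- counts[pr[r, 1]] + wn[r]
        counts[pr[r, 2]] <- counts[pr[r, 2]] + wn[r]
      }
      if (!is.na(tot)) ll_new <- ll_new + groups[[gi]] * log(tot)
    }
    p_new <- counts / (2 * n)
    delta <- max(abs(p_new - p))
    p <- p_new; ll <- ll_new
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  list(freqs = stats::setNames(p, hap_names), em_iterations = it,
       converged = converged, loglik = ll)
}

#' r-squared of the best two-tag haplotype proxy for a target SNP
#'
#' Estimates three-locus haplotype frequencies over (tag_a, tag_b, target)
#' — by direct gamete counting when a phased cohort is supplied, by EM over
#' the 8 haplotypes otherwise — then forms an indicator pseudo-marker for
#' each two-tag allele combination ("carries exactly this tag-pair
#' haplotype") and for the degenerate one-tag haplotypes (e.g. `"1*"`,
#' any haplotype carrying allele 1 of the first tag; these make a target
#' identical to one of the tags its own perfect proxy). The maximum
#' r-squared between a pseudo-marker and the target allele is returned
#' together with the achieving haplotype.
#'
#' @param target_snp target SNP id.
#' @param tag_pair character vector of two tag SNP ids.
#' @param data a `phased_cohort` or a subjects x SNPs dosage matrix.
#' @return list with `r2` (best), `haplotype` (two-character allele string
#'   of the achieving tag pair), `per_haplotype` (data.frame), `converged`.
#' @export
two_tag_haplotype_r2 <- function(target_snp, tag_pair, data) {
  stopifnot(length(tag_pair) == 2)
  snps <- c(tag_pair, target_snp)
  if (inherits(data, "phased_cohort")) {
    gam <- rbind(data$hap_a[, snps, drop = FALSE],
                 data$hap_b[, snps, drop = FALSE])
    key <- apply(gam, 1, paste, collapse = "")
    hap_names <- apply(expand.grid(rep(list(0:1), 3)), 1, paste, collapse = "")
    freqs <- stats::setNames(vapply(hap_names, function(k) mean(key == k), 0),
                             hap_names)
    converged <- TRUE
  } else {
    fit <- em_haplotype_freqs_multi(data[, snps, drop = FALSE])
    freqs <- fit$freqs
    converged <- fit$converged
  }
  alle <- do.call(rbind, strsplit(names(freqs), ""))
  pT <- sum(freqs[alle[, 3] == "1"])
  ## candidate pseudo-markers: the four two-tag haplotypes plus the four
  ## degenerate one-tag haplotypes ("1*" = any haplotype carrying tag_a
  ## allele 1), so a target identical to a tag is its own perfect proxy
  combos <- expand.grid(a = c("0", "1", "*"), b = c("0", "1", "*"),
                        stringsAsFactors = FALSE)
  combos <- combos[!(combos$a == "*" & combos$b == "*"), ]
  res <- data.frame(haplotype = paste0(combos$a, combos$b),
                    freq = NA_real_, r2 = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    sel <- (combos$a[i] == "*" | alle[, 1] == combos$a[i]) &
           (combos$b[i] == "*" | alle[, 2] == combos$b[i])
    pI <- sum(freqs[sel])
    res$freq[i] <- pI
    if (pI <= 0 || pI >= 1 || pT <= 0 || pT >= 1) next
    p11 <- sum(freqs[sel & alle[, 3] == "1"])
    D <- p11 - pI * pT
    res$r2[i] <- min(max(D^2 / (pI * (1 - pI) * pT * (1 - pT)), 0), 1)
  }
  if (all(is.na(res$r2)))
    return(list(r2 = NA_real_, haplotype = NA_character_,
                per_haplotype = res, converged = converged))
  best <- which.max(res$r2)
  list(r2 = res$r2[best], haplotype = res$haplotype[best],
       per_haplotype = res, converged = converged)
}
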