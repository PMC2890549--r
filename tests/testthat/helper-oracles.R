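## Independent oracles and small fixture builders shared across tests.

## Observed-data log-likelihood of two-locus genotype data under haplotype
## frequencies p = (p11, p10, p01, p00), computed from the multinomial over
## the nine genotype cells (vectorized over rows of a grid matrix).
ll_two_locus <- function(ga, gb, P11, P10, P01, P00) {
  cnt <- matrix(0, 3, 3)
  for (i in seq_along(ga)) cnt[ga[i] + 1, gb[i] + 1] <- cnt[ga[i] + 1, gb[i] + 1] + 1
  cell <- list(
    `00` = P00^2,          `01` = 2 * P01 * P00,                `02` = P01^2,
    `10` = 2 * P10 * P00,  `11` = 2 * (P11 * P00 + P10 * P01),  `12` = 2 * P11 * P01,
    `20` = P10^2,          `21` = 2 * P11 * P10,                `22` = P11^2)
  ll <- 0
  for (a in 0:2) for (b in 0:2) {
    n <- cnt[a + 1, b + 1]
    if (n > 0) ll <- ll + n * log(cell[[paste0(a, b)]])
  }
  ll
}

## Brute-force maximum of the two-locus likelihood: coarse grid over the
## haplotype-frequency simplex (step 0.02) refined locally at step 1e-3.
grid_max_ll <- function(ga, gb) {
  eval_grid <- function(step, center = NULL, half = NULL) {
    axis <- function(c0) {
      v <- seq(0, 1, by = step)
      if (!is.null(center)) v <- v[v >= c0 - half - 1e-12 & v <= c0 + half + 1e-12]
      v
    }
    g <- if (is.null(center)) expand.grid(p11 = axis(), p10 = axis(), p01 = axis())
         else expand.grid(p11 = axis(center[1]), p10 = axis(center[2]),
                          p01 = axis(center[3]))
    g <- g[g$p11 + g$p10 + g$p01 <= 1 + 1e-12, , drop = FALSE]
    p00 <- pmax(1 - g$p11 - g$p10 - g$p01, 0)
    ll <- ll_two_locus(ga, gb, g$p11, g$p10, g$p01, p00)
    list(best = as.numeric(g[which.max(ll), ]), ll = max(ll))
  }
  coarse <- eval_grid(0.02)
  fine <- eval_grid(0.001, center = coarse$best, half = 0.025)
  max(coarse$ll, fine$ll)
}

## Direct hypergeometric summation for the two-sided Fisher p-value using
## binomial coefficients only (independent of dhyper).
fisher_oracle <- function(tab) {
  m1 <- tab[1, 1] + tab[1, 2]; m2 <- tab[2, 1] + tab[2, 2]
  k <- tab[1, 1] + tab[2, 1]; N <- m1 + m2
  support <- max(0, k - m2):min(k, m1)
  pr <- choose(m1, support) * choose(m2, k - support) / choose(N, k)
  p_obs <- choose(m1, tab[1, 1]) * choose(m2, k - tab[1, 1]) / choose(N, k)
  min(1, sum(pr[pr <= p_obs * (1 + 1e-9)]))
}

## Two-locus haplotype frequencies implied by a haplotype panel.
panel_pair_freqs <- function(panel, snp_a, snp_b) {
  ha <- panel$haplotypes[, snp_a]; hb <- panel$haplotypes[, snp_b]
  f <- function(x, y) sum(panel$frequencies[ha == x & hb == y])
  c(p11 = f(1, 1), p10 = f(1, 0), p01 = f(0, 1), p00 = f(0, 0))
}

## Random two-locus genotype dataset (for EM property tests).
random_geno_pair <- function(n, seed) {
  set.seed(seed)
  pa <- runif(1, 0.15, 0.85); pb <- runif(1, 0.15, 0.85)
  repeat {
    ga <- rbinom(n, 2, pa); gb <- rbinom(n, 2, pb)
    if (length(unique(ga)) > 1 && length(unique(gb)) > 1) break
  }
  list(ga = ga, gb = gb)
}

## Panel of k perfect r2-clusters (all SNPs within a cluster identical).
cluster_panel <- function(sizes, n_hap = 300, freq = 0.3, seed = 1) {
  set.seed(seed)
  base <- matrix(rbinom(n_hap * length(sizes), 1, freq), n_hap, length(sizes))
  hap <- base[, rep(seq_along(sizes), sizes), drop = FALSE]
  colnames(hap) <- sprintf("s%02d", seq_len(ncol(hap)))
  haplotype_panel(colnames(hap), hap, rep(1 / n_hap, n_hap))
}

## Packaged synthetic example cohort (printed-margin reconstruction).
example_fixture <- function() {
  ext <- system.file("extdata", package = "aseassoc")
  list(covariates = read_covariates(file.path(ext, "example_covariates.csv")),
       calls = utils::read.delim(file.path(ext, "example_ase_calls.tsv"),
                                 stringsAsFactors = FALSE),
       genotypes = read_genotypes(file.path(ext, "example_genotypes.tsv")),
       freqs = utils::read.csv(file.path(ext, "example_assoc_freqs.csv"),
                               stringsAsFactors = FALSE))
}

marker_ids <- c("rs334348", "rs334349", "rs1590", "rs7871490")
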