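test_that("EM reduces to direct gamete counting when phase is unambiguous", {
  pan <- haplotype_panel(c("a", "b"), rbind(c(0, 0), c(1, 1), c(1, 0)),
                         c(0.5, 0.3, 0.2))
  co <- draw_subjects(pan, 400, seed = 7)
  g <- cohort_genotypes(co)
  dh <- g[, "a"] == 1 & g[, "b"] == 1
  keep <- !dh
  em <- em_haplotype_freqs(g[keep, "a"], g[keep, "b"])
  direct <- count_haplotype_freqs(co$hap_a[keep, c("a", "b")],
                                  co$hap_b[keep, c("a", "b")])
  expect_equal(em$hap_freqs, direct, tolerance = 1e-8)
  expect_true(em$converged)
})

test_that("identical genotype columns give perfect correlation", {
  g <- c(0, 1, 2, 1, 0, 2, 1, 1, 0, 2, 2, 0)
  pl <- pair_ld(g, g)
  expect_equal(pl$hap_freqs[["p11"]], pl$allele_freqs[["pA"]], tolerance = 1e-8)
  expect_lt(pl$hap_freqs[["p10"]] + pl$hap_freqs[["p01"]], 1e-8)
  expect_equal(pl$r2, 1, tolerance = 1e-8)
})

test_that("EM log-likelihood is monotone and attains the brute-force maximum", {
  for (s in 1:5) {
    d <- random_geno_pair(n = sample(4:12, 1), seed = 1000 + s)
    em <- em_haplotype_freqs(d$ga, d$gb)
    trace <- attr(em, "loglik_trace")
    expect_true(all(diff(trace) >= -1e-12))
    p <- em$hap_freqs
    ll_em <- ll_two_locus(d$ga, d$gb, p[["p11"]], p[["p10"]], p[["p01"]], p[["p00"]])
    expect_gte(ll_em, grid_max_ll(d$ga, d$gb) - 1e-6)
  }
  expect_error(em_haplotype_freqs(c(1, NA), c(NA, 1)), "insufficient")
})

test_that("LD statistics match closed-form expectations", {
  ## hand-worked: pA = pB = 0.5, p11 = 0.35
  st <- ld_stats(c(p11 = 0.35, p10 = 0.15, p01 = 0.15, p00 = 0.35))
  expect_equal(st$D, 0.10)
  expect_equal(st$r2, 0.16)
  expect_equal(st$D_prime, 0.4)
  ## coupling limit: p11 = pA = pB
  st2 <- ld_stats(c(p11 = 0.3, p10 = 0, p01 = 0, p00 = 0.7))
  expect_equal(st2$D_prime, 1)
  expect_equal(st2$r2, 1)
  ## equilibrium: p11 = pA * pB
  st3 <- ld_stats(c(p11 = 0.12, p10 = 0.28, p01 = 0.18, p00 = 0.42))
  expect_equal(st3$D, 0, tolerance = 1e-12)
  expect_equal(st3$r2, 0, tolerance = 1e-12)
  ## monomorphic locus: r2 explicitly undefined, not zero
  st4 <- ld_stats(c(p11 = 0, p10 = 0, p01 = 0.4, p00 = 0.6))
  expect_false(st4$r2_defined)
  expect_true(is.na(st4$r2))
})

test_that("r2 is symmetric and invariant to allele relabeling", {
  for (s in 1:10) {
    d <- random_geno_pair(40, seed = 2000 + s)
    r_ab <- pair_ld(d$ga, d$gb)$r2
    r_ba <- pair_ld(d$gb, d$ga)$r2
    expect_equal(r_ab, r_ba, tolerance = 1e-12)
    expect_equal(pair_ld(2 - d$ga, d$gb)$r2, r_ab, tolerance = 1e-9)
    expect_equal(pair_ld(d$ga, 2 - d$gb)$r2, r_ab, tolerance = 1e-9)
  }
})

test_that("greedy tagging recovers planted cluster structure", {
  ## one perfect cluster: a single tag suffices
  pan1 <- cluster_panel(sizes = 4, seed = 3)
  g1 <- cohort_genotypes(draw_subjects(pan1, 300, seed = 4))
  ts1 <- greedy_tag(g1)
  expect_equal(length(ts1$tags), 1)
  expect_equal(ts1$n_covered_at_threshold, 4)

  ## three clusters: exactly three tags, membership recovered
  pan3 <- cluster_panel(sizes = c(3, 3, 2), seed = 9)
  g3 <- cohort_genotypes(draw_subjects(pan3, 400, seed = 5))
  ts3 <- greedy_tag(g3)
  expect_equal(length(ts3$tags), 3)
  expect_equal(ts3$n_covered_at_threshold, 8)
  ## each target's proxy sits in its own cluster
  cluster_of <- rep(1:3, c(3, 3, 2))
  names(cluster_of) <- sprintf("s%02d", 1:8)
  for (i in seq_len(nrow(ts3$proxy_map))) {
    r <- ts3$proxy_map[i, ]
    if (r$proxy_type %in% c("self", "single"))
      expect_equal(cluster_of[[r$target]], cluster_of[[r$proxy]])
  }

  ## independent SNPs: every common SNP tags itself
  pan0 <- haplotype_panel(c("a", "b"),
                          rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)), rep(.25, 4))
  g0 <- cohort_genotypes(draw_subjects(pan0, 500, seed = 6))
  ts0 <- greedy_tag(g0)
  expect_setequal(ts0$tags, c("a", "b"))

  ## everything below the MAF cutoff: empty tag set with a warning
  rare <- matrix(c(rep(0L, 99), 1L), 50, 2, dimnames = list(NULL, c("x", "y")))
  expect_warning(ts_e <- greedy_tag(rare), "MAF")
  expect_equal(length(ts_e$tags), 0)

  ## exhaustive search agrees on the 3-cluster panel
  ts_x <- greedy_tag(g3, exhaustive = TRUE)
  expect_equal(length(ts_x$tags), 3)
})

test_that("two-tag haplotype proxies rescue AND-structured targets", {
  ## target allele = AND of two independent tags at frequency 0.5
  set.seed(12)
  a <- rbinom(500, 1, .5); b <- rbinom(500, 1, .5)
  hap <- cbind(a = a, b = b, t = as.integer(a & b))
  pan <- haplotype_panel(colnames(hap), hap, rep(1 / 500, 500))
  co <- draw_subjects(pan, 600, seed = 8)
  g <- cohort_genotypes(co)

  ## phased route: direct counting
  tt <- two_tag_haplotype_r2("t", c("a", "b"), co)
  expect_equal(tt$r2, 1, tolerance = 1e-9)
  expect_equal(tt$haplotype, "11")
  ## unphased route: three-locus EM agrees
  tt_em <- two_tag_haplotype_r2("t", c("a", "b"), g)
  expect_equal(tt_em$r2, 1, tolerance = 1e-6)
  expect_true(tt_em$converged)
  ## while no single tag covers the target
  expect_lt(pair_ld(g[, "a"], g[, "t"])$r2, 0.8)
  expect_lt(pair_ld(g[, "b"], g[, "t"])$r2, 0.8)

  ## self proxy: target identical to a tag
  ts_self <- two_tag_haplotype_r2("a", c("a", "b"), co)
  expect_equal(ts_self$r2, 1, tolerance = 1e-9)

  ## independent target: near-zero best proxy r2
  set.seed(13)
  hap2 <- cbind(a = rbinom(400, 1, .5), b = rbinom(400, 1, .5),
                t = rbinom(400, 1, .5))
  pan2 <- haplotype_panel(colnames(hap2), hap2, rep(1 / 400, 400))
  co2 <- draw_subjects(pan2, 800, seed = 9)
  expect_lt(two_tag_haplotype_r2("t", c("a", "b"), co2)$r2, 0.05)
})

test_that("coverage report and tagging soundness hold", {
  ## rescue panel: two 2-SNP clusters plus an AND target
  set.seed(14)
  a <- rbinom(400, 1, .5); b <- rbinom(400, 1, .5)
  hap <- cbind(a1 = a, a2 = a, b1 = b, b2 = b, tt = as.integer(a & b))
  pan <- haplotype_panel(colnames(hap), hap, rep(1 / 400, 400))
  g <- cohort_genotypes(draw_subjects(pan, 600, seed = 10))
  ts <- greedy_tag(g)
  cr <- coverage_report(ts)
  expect_equal(cr$n_covered_at_threshold, cr$n_common)
  expect_gte(cr$mean_r2, ts$r2_threshold)
  expect_true("two_tag" %in% ts$proxy_map$proxy_type)
  expect_true(all(diff(cr$table$r2) <= 0))

  ## stored proxy r2 values recompute from genotypes
  for (i in seq_len(nrow(ts$proxy_map))) {
    r <- ts$proxy_map[i, ]
    rec <- switch(r$proxy_type,
                  self = 1,
                  single = pair_ld(g[, r$target], g[, r$proxy])$r2,
                  two_tag = two_tag_haplotype_r2(
                    r$target, strsplit(r$proxy, "+", fixed = TRUE)[[1]], g)$r2)
    expect_equal(rec, r$r2, tolerance = 1e-10)
  }

  ## saturated tagging: every common SNP its own tag -> mean r2 = 1
  pan0 <- haplotype_panel(c("a", "b"),
                          rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)), rep(.25, 4))
  g0 <- cohort_genotypes(draw_subjects(pan0, 400, seed = 11))
  expect_equal(coverage_report(greedy_tag(g0))$mean_r2, 1)

  ## degenerate single-SNP panel
  g1 <- matrix(rbinom(200, 2, 0.3), ncol = 1, dimnames = list(NULL, "only"))
  ts1 <- greedy_tag(g1)
  expect_equal(ts1$n_common, 1)
  expect_equal(ts1$mean_r2, 1)
})
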