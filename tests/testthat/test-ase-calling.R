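pm <- function(subject, snp, template, common, rare)
  list(subject_id = subject, snp_id = snp, template = template,
       area_common = common, area_rare = rare)

test_that("normalized ratio follows the cDNA-over-gDNA definition", {
  expect_equal(normalized_ratio(pm("s1", "m1", "gDNA", 1000, 1000),
                                pm("s1", "m1", "cDNA", 1000, 1000)), 1.0)
  expect_equal(normalized_ratio(pm("s1", "m1", "gDNA", 1000, 1000),
                                pm("s1", "m1", "cDNA", 1500, 500)), 3.0)
  expect_equal(normalized_ratio(pm("s1", "m1", "gDNA", 1000, 900),
                                pm("s1", "m1", "cDNA", 800, 1200)), 0.6)
  expect_error(normalized_ratio(pm("s1", "m1", "gDNA", 1, 1),
                                pm("s2", "m1", "cDNA", 1, 1)), "pairing")
  expect_error(normalized_ratio(pm("s1", "m1", "cDNA", 1, 1),
                                pm("s1", "m1", "cDNA", 1, 1)), "template")
  expect_error(normalized_ratio(pm("s1", "m1", "gDNA", 0, 1),
                                pm("s1", "m1", "cDNA", 1, 1)), "positive")
})

test_that("normalized ratio is scale invariant and label-swap reciprocal", {
  set.seed(42)
  for (i in 1:50) {
    a <- runif(4, 100, 5000)      # gDNA common/rare, cDNA common/rare
    k <- runif(2, 0.1, 10)        # one positive scale per measurement
    r0 <- normalized_ratio(pm("s", "m", "gDNA", a[1], a[2]),
                           pm("s", "m", "cDNA", a[3], a[4]))
    r_scaled <- normalized_ratio(pm("s", "m", "gDNA", k[1] * a[1], k[1] * a[2]),
                                 pm("s", "m", "cDNA", k[2] * a[3], k[2] * a[4]))
    expect_equal(r_scaled, r0, tolerance = 1e-12)
    r_swap <- normalized_ratio(pm("s", "m", "gDNA", a[2], a[1]),
                               pm("s", "m", "cDNA", a[4], a[3]))
    expect_equal(r_swap, 1 / r0, tolerance = 1e-12)
  }
})

test_that("replicate averaging reports n and flags incomplete designs", {
  expect_equal(replicate_mean(rep(2, 4))$mean_ratio, 2.0)
  expect_equal(replicate_mean(c(1.2, 1.4, 1.6, 1.8))$mean_ratio, 1.5)
  expect_warning(res <- replicate_mean(c(0.5, 2.0)), "incomplete")
  expect_equal(res$mean_ratio, 1.25)
  expect_equal(res$n_ratios, 2)
  expect_error(replicate_mean(numeric(0)), "empty")
})

test_that("classification thresholds are inclusive and the band is asymmetric", {
  expect_equal(classify_ase(1.50), "positive")
  expect_equal(classify_ase(0.67), "positive")
  expect_equal(classify_ase(1.0), "negative")
  expect_equal(classify_ase(0.68), "negative")
  expect_equal(classify_ase(1 / 1.5), "positive")     # 0.666... <= 0.67
  expect_equal(classify_ase(1.50, inclusive = FALSE), "negative")
  expect_equal(classify_ase(0.67, inclusive = FALSE), "negative")
  expect_error(classify_ase(-1), "positive")
  ## band characterization: negative exactly on (0.67, 1.5)
  for (x in c(0.6701, 0.9, 1.1, 1.4999)) expect_equal(classify_ase(x), "negative")
  for (x in c(0.1, 0.67, 1.5, 3)) expect_equal(classify_ase(x), "positive")
})

test_that("informativeness requires at least one heterozygous marker", {
  expect_false(informative_subject(c(m1 = 0, m2 = 0, m3 = 2, m4 = NA))$informative)
  r <- informative_subject(c(m1 = 1, m2 = 0, m3 = 0, m4 = 0))
  expect_true(r$informative)
  expect_equal(r$het_markers, "m1")
  r4 <- informative_subject(c(m1 = 1, m2 = 1, m3 = 1, m4 = 1))
  expect_equal(length(r4$het_markers), 4)
})

test_that("cohort calling counts constructed positives exactly", {
  ## 118 subjects, one marker; 11 planted with a ratio passing the threshold
  n <- 118
  ids <- sprintf("P%03d", 1:n)
  geno <- matrix(1L, n, 1, dimnames = list(ids, "m1"))
  fold <- rep(1.0, n); fold[c(2, 10, 20:27, 50)] <- 2.0   # 11 positives
  peaks <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(subject_id = ids[i], snp_id = "m1",
               template = rep(c("gDNA", "cDNA"), each = 4),
               prep = rep(c(1, 1, 2, 2), 2), duplicate = rep(c(1, 2, 1, 2), 2),
               area_allele0 = c(rep(1000, 4), rep(1000 * fold[i], 4)),
               area_allele1 = rep(1000, 8), stringsAsFactors = FALSE)
  }))
  calls <- call_cohort(peaks, geno, "m1")
  expect_equal(sum(calls$calls$call == "positive"), 11)
  expect_equal(sum(calls$calls$call == "negative"), 107)
  ## orientation: allele 1 is universally het here, common allele is allele 0
  expect_equal(calls$per_snp$mean_ratio[calls$per_snp$subject_id == "P002"], 2.0)
})

test_that("cohort calling flags discordant multi-marker subjects and QC failures", {
  geno <- matrix(c(1L, 1L), 1, 2, dimnames = list("s1", c("m1", "m2")))
  mk <- function(snp, fold) data.frame(
    subject_id = "s1", snp_id = snp,
    template = rep(c("gDNA", "cDNA"), each = 4),
    prep = rep(c(1, 1, 2, 2), 2), duplicate = rep(c(1, 2, 1, 2), 2),
    area_allele0 = c(rep(1000, 4), rep(1000 * fold, 4)),
    area_allele1 = rep(1000, 8), stringsAsFactors = FALSE)
  calls <- call_cohort(rbind(mk("m1", 2), mk("m2", 0.5)), geno, c("m1", "m2"))
  expect_equal(calls$calls$call, "positive")
  expect_false(calls$calls$concordant)

  ## peaks for a homozygous marker are a QC error
  geno2 <- matrix(c(1L, 0L), 1, 2, dimnames = list("s1", c("m1", "m2")))
  expect_error(call_cohort(rbind(mk("m1", 2), mk("m2", 1)), geno2, c("m1", "m2")),
               "QC error")

  ## subjects without any heterozygous marker are uninformative
  geno3 <- rbind(s1 = c(1L, 1L), s2 = c(0L, 2L))
  colnames(geno3) <- c("m1", "m2")
  calls3 <- call_cohort(rbind(mk("m1", 2), mk("m2", 0.5)), geno3, c("m1", "m2"))
  expect_equal(calls3$calls$call[calls3$calls$subject_id == "s2"], "uninformative")
})

test_that("shared gDNA normalization is used when per-slot gDNA is absent", {
  geno <- matrix(1L, 1, 1, dimnames = list("s1", "m1"))
  peaks <- data.frame(subject_id = "s1", snp_id = "m1",
                      template = c("gDNA", rep("cDNA", 4)),
                      prep = c(1, 1, 1, 2, 2), duplicate = c(1, 1, 2, 1, 2),
                      area_allele0 = c(1000, rep(1800, 4)),
                      area_allele1 = c(900, rep(1000, 4)),
                      stringsAsFactors = FALSE)
  calls <- call_cohort(peaks, geno, "m1")
  expect_equal(calls$per_snp$mean_ratio, (1800 / 1000) / (1000 / 900))
  expect_equal(calls$per_snp$n_ratios, 4L)
})

test_that("noise-free end-to-end ratios hit the planted fold exactly", {
  for (f in c(0.5, 0.8)) {
    sim <- simulate_cohort(sim_config(seed = 17, sigma_gdna = 0, sigma_cdna = 0,
                                      effect_fold = f))
    calls <- call_cohort(sim$peaks, sim$genotypes, sim$config$marker_snp_ids)
    m <- merge(calls$per_snp, sim$truth$subjects, by = "subject_id")
    carried <- m[m$causal_het, ]
    expect_true(all(abs(carried$mean_ratio - f) < 1e-12 |
                      abs(carried$mean_ratio - 1 / f) < 1e-12))
    expect_true(all(abs(m$mean_ratio[!m$causal_het] - 1) < 1e-12))
    expect_identical(calls$calls$call, sim$truth$subjects$expected_call)
  }
})

test_that("call sensitivity is non-increasing in effect_fold under fixed noise", {
  sens <- vapply(c(0.5, 0.7, 0.9), function(f) {
    hits <- 0; total <- 0
    for (s in 1:30) {
      sim <- simulate_cohort(sim_config(seed = 300 + s, effect_fold = f))
      calls <- call_cohort(sim$peaks, sim$genotypes, sim$config$marker_snp_ids)
      ## sensitivity relative to assayable carriers of the reduced haplotype
      carrier <- sim$truth$subjects$causal_het & sim$truth$subjects$informative
      hits <- hits + sum(calls$calls$call == "positive" & carrier)
      total <- total + sum(carrier)
    }
    hits / total
  }, 0)
  expect_true(all(diff(sens) <= 0))
})

test_that("cohort summary handles degenerate and unknown strata", {
  cov <- data.frame(subject_id = c("a", "b", "c"),
                    sex = c("Female", "Male", NA),
                    location = c("Colon", "Rectum", "Colon"),
                    stage = c("I", "IV", "II"),
                    stringsAsFactors = FALSE)
  calls <- data.frame(subject_id = c("a", "b", "c"),
                      call = rep("negative", 3), stringsAsFactors = FALSE)
  expect_warning(s <- summarize_cohort(calls, cov), "Unknown")
  expect_equal(s$n_positive, 0)
  expect_true(all(s$counts$pct_ase_pos == 0))
  expect_true("Unknown" %in% s$counts$level[s$counts$covariate == "sex"])
})
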