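---
title: "Calling decreased allelic expression and testing SNP association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling decreased allelic expression and testing SNP association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aseassoc)
```

## The phenotype and its measurement model

A cis-regulatory variant that lowers transcription of the haplotype carrying
it produces *constitutively decreased allelic expression*: in a heterozygous
carrier, one allele's transcript is systematically under-represented. The
assay this package models distinguishes the two transcripts at a
heterozygous marker SNP in the transcribed sequence (typically the 3'-UTR)
and quantifies each allele as a fluorescence peak area, in cDNA and — to
correct allele-specific amplification or extension bias — in genomic DNA,
where both alleles are present in exactly one copy.

The per-replicate statistic is the normalized allelic ratio

$$R \;=\; \frac{\text{cDNA: area}_{\text{common}}/\text{area}_{\text{rare}}}
              {\text{gDNA: area}_{\text{common}}/\text{area}_{\text{rare}}},$$

and the subject-by-marker value is the arithmetic mean of the replicate
ratios: the design is two independent cDNA preparations, each in duplicate,
so four ratios per marker (`replicate_mean()` warns when fewer are
available). A marker is *informative* only in heterozygotes; a subject with
no heterozygous marker cannot be assayed and is called `uninformative`.

The phenotype call (`classify_ase()`) is **positive** when the mean ratio is
at or beyond either threshold, $R \ge 1.5$ or $R \le 0.67$, inclusive by
default and configurable (`inclusive = FALSE` gives the strict reading).
Note the band is deliberately not reciprocal: $1/1.5 = 0.6\overline{6} \le
0.67$ is positive.

Three conventions are choices of this package where the assay literature is
silent, fixed as defaults and exposed as parameters:

- **Orientation.** "Common" is the higher-frequency allele *within the
  cohort's genotypes at that SNP* (ties to allele 0). Exchanging
  common and rare in both templates maps $R \mapsto 1/R$, so orientation
  only reflects the ratio about 1.
- **Multiple informative markers.** A subject is positive if *any*
  informative marker passes. Per-marker ratios are reported, and a subject
  whose markers disagree in direction (one $\ge 1.5$, another $\le 0.67$)
  is flagged discordant rather than averaged across markers — common/rare
  orientation is not phase-consistent across markers, so cross-marker
  averaging would mix orientations.
- **gDNA pairing.** cDNA replicate slot *k* is normalized by gDNA slot *k*
  when per-slot gDNA exists; otherwise all cDNA slots share the mean of the
  available gDNA ratios (exactly "the" single gDNA ratio when only one was
  run). Both readings of a shared-versus-per-replicate gDNA normalization
  are supported because assay write-ups support both.

## Linkage disequilibrium and tag selection

`em_haplotype_freqs()` estimates two-locus haplotype frequencies from
unphased 0/1/2 dosages by EM. Only double heterozygotes are phase-ambiguous;
the E-step splits them between coupling and repulsion gamete pairs in
proportion to $p_{11}p_{00}$ versus $p_{10}p_{01}$. Numerical choices:
initialization at the linkage-equilibrium product of allele frequencies,
convergence when the largest frequency change is below $10^{-10}$, a cap of
1000 iterations with a `converged` flag, no random restarts (the
two-locus likelihood is well-behaved and the test suite verifies against
brute-force grid maximization), and pairwise-complete subjects only.
`ld_stats()` computes $D = p_{11} - p_A p_B$,
$r^2 = D^2/(p_A q_A p_B q_B)$ (clipped to $[0,1]$ against floating error)
and $D'$; a monomorphic locus yields an explicit *undefined* marker, never a
silent 0.

`greedy_tag()` selects tags so every *common* SNP (MAF $\ge 0.05$, the
HapMap-era convention; configurable) has a proxy with $r^2 > 0.8$. The
greedy objective is maximum new coverage, with ties broken by higher MAF
then input order — the practice of pairwise tagger designs. When only
self-coverage remains, each uncovered SNP is first offered **two-tag
haplotype rescue**: three-locus haplotype frequencies over (tag a, tag b,
target) — direct gamete counting on phased input, an eight-haplotype EM
otherwise — define indicator pseudo-markers for each two-tag haplotype, and
the best pseudo-marker's $r^2$ with the target is used. The candidate set
includes the degenerate one-tag haplotypes (`"1*"` = any haplotype carrying
allele 1 of the first tag), so a target identical to a tag is its own
perfect proxy. Only SNPs that rescue fails become tags of their own. An
exhaustive minimal-cover search is available for panels of at most 15
common SNPs. `coverage_report()` summarizes the mean best-proxy $r^2$
(tags contribute 1) and the count covered at the threshold.

## Association testing

The phenotype contrast is ASE-positive subjects against *the remainder of
the cohort* — uninformative subjects included in the remainder by default
(`drop_uninformative = TRUE` excludes them). Per SNP, `allele_table()`
counts two alleles per subject (allelic coding; carrier/dominant coding
behind a flag), `pearson_chi2()` applies the closed form
$N(ad-bc)^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))$ with 1 df and no continuity
correction, and the odds ratio is the cross-product $(ad)/(bc)$, printed as
the literal `n/a` when a zero cell makes it undefined (Haldane–Anscombe
+0.5 behind a flag). No multiple-testing adjustment is applied by default:
the scan mirrors published candidate-locus tables that report raw p-values
across ~19 SNPs. Hardy–Weinberg equilibrium is *not* tested or assumed; the
allelic test treats alleles as independent, which inflates significance
under strong HW departure — a documented caveat of this test family.
`odds_ratio_from_freqs()` recovers the odds ratio implied by two group
frequencies, $\big(f_1/(1{-}f_1)\big)/\big(f_2/(1{-}f_2)\big)$, which is how
published odds ratios can be checked against printed two-decimal
frequencies (agreement only to the rounding slack of those inputs, roughly
3% relative).

`fisher_exact()` implements the two-sided Fisher test by exact enumeration
over the hypergeometric support with fixed margins, using the
probability-mass rule — the sum of probabilities of all tables no more
probable than the observed one, with relative tolerance $10^{-9}$ on the
comparison. A zero margin leaves a single support point and $p = 1$. This
rule (the R convention) is what published clinical-contrast p-values in
this literature reproduce.

## What the synthetic cohort emulates

`simulate_cohort()` generates cohorts with the statistical structure the
analysis assumes, at the study's scale by default:

| parameter | default | rationale |
|---|---|---|
| `n_subjects` | 118 | the case-series size the pipeline targets |
| locus / marker SNPs | 19 + 4 | genotyped locus panel plus transcribed 3'-UTR markers |
| `causal_freq` | 0.10 | cis-regulatory allele frequency (per-study plausible value) |
| `effect_fold` | 0.5 | halved expression of the carrier haplotype |
| `marker_freq` | 0.10 | see prevalence arithmetic below |
| `sigma_cdna`, `sigma_gdna` | 0.10, 0.05 | sd of log peak area; platform noise is unpublished, so these are calibration choices, with gDNA assumed quieter than cDNA |
| `n_preps`, `n_duplicates` | 2, 2 | the two-preparations-in-duplicate design |
| `baseline_area` | 1000 | arbitrary fluorescence units |

The haplotype pool is 100 equifrequent haplotypes; each SNP's allele-1
carriers are an independent random subset of size `round(freq × 100)`, so
unrelated SNPs sit near linkage equilibrium with realized frequencies
within 1/200 of target, and the causal SNP's carrier set is copied onto a
designated proxy SNP to plant an $r^2 = 1$ proxy. Subjects are two
independent draws from the pool (Hardy–Weinberg); covariates are drawn
independently of genotype and phenotype, so all clinical contrasts are null
by construction. Expression of a haplotype is 1.0, multiplied by
`effect_fold` if it carries the causal allele; expected cDNA peak areas are
proportional to the expression of the haplotype carrying each allele, gDNA
areas are flat, and every area receives multiplicative lognormal noise
$\exp N(0, \sigma)$ — fluorescence is positive and its errors
multiplicative.

Prevalence arithmetic behind the defaults: a subject is called positive
when heterozygous at the causal SNP *and* at $\ge 1$ marker. Under
independence, $P(\text{causal het}) = 2(0.1)(0.9) = 0.18$ and
$P(\ge 1\ \text{het marker}) = 1 - (1 - 0.18)^4 \approx 0.55$, giving the
documented `target_prevalence` of 0.10 — the high single digits to ~10%
range reported for this phenotype in colorectal-cancer case series. The
calibration test averages the positive fraction over 200 seeded cohorts.

One master seed drives derived streams (`derive_seed()`) for panel,
subjects, noise and covariates, so stages can be rerun in isolation and
identical configurations are byte-identical end to end.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: recombination (LD arises only from the
haplotype pool), genotyping error and missingness, population structure or
admixture, prep-level random effects or batch drift in the assay,
somatically acquired variation, and any genotype–covariate correlation.
Noise-free recovery and seeded-power results are statements about the model,
not about any laboratory platform.

## Degenerate inputs and edge behavior

Measurements for a homozygous marker are a QC error (listing the offending
rows), not silently dropped. Monomorphic SNPs yield undefined $r^2$ and an
annotated, untestable association row while the scan continues. Empty
phenotype groups, zero table margins and boundary frequencies raise typed
validation/computation errors or return explicit `n/a`, never fabricated
zeros. Report percentages use half-up rounding at one decimal; frequencies
print at two decimals and odds ratios at one, matching the precision of the
published tables this layout mirrors.

## Validation problem sizes

The test suite exercises: EM against coarse-plus-refined grid maximization
of the two-locus likelihood on 20 random datasets of at most 12 subjects
(the grid maximum can only underestimate the true maximum, so the check is
EM log-likelihood $\ge$ grid maximum $- 10^{-6}$); Fisher enumeration
against direct binomial-coefficient summation on every 2×2 table with total
$\le 60$; the chi-square closed form on 1000 random tables; planted-cluster
tag recovery and AND-gate two-tag rescue; 100 seeded study-scale cohorts
for causal-variant recovery (minimum association p at the causal SNP or its
planted proxy) with noise-free sensitivity and specificity checks; 200
cohorts for prevalence calibration; and 200 phenotype permutations for
chi-square type-I calibration. These sizes were chosen to make each
property statistically meaningful while keeping the default suite fast.

## Known limitations

- The ASE statistic is peak-area based; read-count ASE from sequencing has
  different error structure and is out of scope.
- The allelic association test ignores within-subject allele dependence;
  with 11 cases, expected cell counts are small and exact or permutation
  procedures are advisable companions (the permutation calibration test
  shows the nominal level holds under the simulator's null).
- Tagging is pairwise-plus-two-tag only; general multimarker tagging and
  haplotype phasing beyond three loci are not implemented.
- Published odds ratios derived from unrounded counts cannot be recovered
  exactly from two-decimal printed frequencies; agreement is bounded by the
  input rounding (~3% relative).
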