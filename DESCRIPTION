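Package: aseassoc
Title: Allele-Specific Expression Calling and Allelic Association at a
    Candidate Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting constitutively decreased allelic expression
    of a candidate gene from allelic peak-area assays and for testing locus
    SNPs for association with the resulting phenotype. Implements normalized
    cDNA/gDNA allelic-ratio computation with replicate averaging and
    threshold-based phenotype calls, two-locus EM haplotype-frequency
    estimation with D, D' and r-squared, greedy tag-SNP selection with
    two-tag haplotype rescue, allelic chi-square association with odds
    ratios, and Fisher exact tests for clinical contingency tables. A
    synthetic-cohort generator with a planted cis-regulatory variant and a
    lognormal peak-noise model supports end-to-end validation and power
    exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
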