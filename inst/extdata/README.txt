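Synthetic example data bundled with aseassoc.

These files are a synthetic reconstruction of the summary structure of a
published colorectal-cancer ASE case series (118 subjects): individual-level
rows were generated to match published marginal counts and group allele
frequencies, not taken from any real subjects.

example_covariates.csv   clinical covariates (age, sex, ethnicity, tumor
                         location, stage, family history)
example_ase_calls.tsv    per-subject ASE phenotype call
                         (11 positive / 63 negative / 44 uninformative)
example_genotypes.tsv    0/1/2 dosages at the four transcribed 3'-UTR marker
                         SNPs and the signal-sequence deletion variant
                         (sig9A6A); 74/118 subjects are marker-heterozygous
example_assoc_freqs.csv  group allele-2 frequencies (ASE-positive vs rest)
                         for 19 locus SNPs, 2-decimal precision
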