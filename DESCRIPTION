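Package: polyscore
Title: Polygenic Risk Scores from Genotype Probabilities with
    Strand-Ambiguous SNP Rescue
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes polygenic risk scores (PRS) for a target cohort from
    discovery GWAS summary statistics at multiple p-value thresholds in a
    single pass. Scores are built from imputed genotype posterior
    probabilities (expected effect-allele dosage 2*p(AA) + p(AB)) or hard
    calls, read from Oxford GEN/SAMPLE or VCF (GT or GP fields). Effect
    alleles are reconciled against the target alleles including the
    reverse-complement strand, and strand-ambiguous (A/T, C/G) SNPs are
    rescued by comparing discovery and target allele frequencies instead of
    being discarded, excluding frequencies between 0.4 and 0.6 where
    assignment is uncertain. Includes a per-threshold SNP log with discard
    reasons, per-sample SNP counts and averaged scores, phenotype regression
    across thresholds with best-fit selection, and a synthetic panel
    generator with a brute-force scoring oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
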