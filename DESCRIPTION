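Package: cystsev
Title: Severity Scoring of Cystinuria Mutations from Variant Effect Predictions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for associating protein-level mutations in the cystinuria
    genes SLC3A1 (rBAT) and SLC7A9 (b(0+)AT) with disease severity. Variant
    effect predictor scores (SIFT, PolyPhen2, MutationAssessor, FATHMM,
    Condel, CADD) are dichotomised into mild (1) or severe (2) calls using
    per-method thresholds with a threshold-stabilisation search; per-patient
    severity scores are aggregated under the gene's inheritance model
    (additive for autosomal dominant SLC7A9, minimum-allele for autosomal
    recessive SLC3A1); phenotype distributions are compared between severity
    groups with an exact Wilcoxon rank-sum test and Bonferroni correction;
    and disease-associated variant sets are contrasted with population
    variation on allele frequency, conservation and predicted stability.
    Includes HGVS p. parsing, amino-acid substitution-class cross-tabulation,
    and a seeded synthetic-cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    readr,
    rlang,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
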