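Package: ccia
Title: Cross-Cohort Integrative Analysis of Microbiome and Metabolome Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Cross-cohort case-control analysis of gut metagenomic and
    metabolomic profiles: cohort-blocked permutation Wilcoxon tests with
    generalized fold change and KEGG orthology enrichment, OPLS-DA with VIP
    scores and label-permutation validation, iterative feature elimination
    with random-forest evaluation across within-cohort, cohort-to-cohort and
    leave-one-cohort-out designs, alpha/beta diversity with PERMANOVA and
    per-feature confounder variance partitioning, multi-omics biological
    correlation (MOBC) maps linking differential metabolites to
    enzyme-encoding KO genes with top taxonomic contributors, and a seeded
    multi-cohort simulator with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    ranger,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
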