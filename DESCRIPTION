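Package: defensinCNV
Title: Beta-Defensin Copy-Number Genotyping and Cervicovaginal
    Antimicrobial Assay Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calls integer beta-defensin (DEFB4 locus) gene copy number from
    paralogue ratio test (PRT) peak-area tables by reference-panel regression
    calibration and pooled Gaussian maximum-likelihood integer selection.
    Processes ELISA and bactericidal kill-assay readings: limit-of-detection
    censoring by LOD/sqrt(2) substitution, total-protein normalisation, and
    the percent-kill statistic with triplicate aggregation. Provides a
    pairwise Spearman rank-correlation association layer with exclusion
    rules, delivery-outcome stratification and Mann-Whitney group comparison,
    and a seeded synthetic-cohort generator that emulates the joint
    genotype/biomarker/outcome structure so the whole pipeline can be
    validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
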