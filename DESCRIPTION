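Package: chemgenscreen
Title: Chemical-Genetic CRISPRi Screen Scoring and Mutation-Sensitivity Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pooled CRISPRi chemical-genetic screens:
    exact-match sgRNA counting from FASTQ, growth (gamma) and drug-sensitivity
    (rho) phenotypes normalized to non-targeting controls and population
    doublings, gene-level Mann-Whitney scoring against negative-control
    pseudo-genes, discriminant-score hit calling with transcription start site
    collapse, and a synthetic-screen simulator with known ground truth for
    validating every stage. Also implements the companion mutation-versus-
    drug-sensitivity analysis: MAF-style variant filtering (variant class and
    CADD Phred thresholds) to a binary gene-by-cell-line matrix, per-gene and
    gene-set Wilcoxon rank-sum association with IC50 values, and four-parameter
    logistic IC50 fitting from viability plates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    purrr,
    rlang,
    yaml,
    jsonlite,
    ggplot2,
    Biostrings,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
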