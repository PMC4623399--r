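Package: energyomics
Title: Tri-Omic Differential Analysis for High-Energy Plant Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical machinery for comparing a high-ATP transgenic plant
    line against wild type across three omic layers: compartment-aware RPKM
    quantification of nuclear, mitochondrial and chloroplast transcripts; an
    exact two-library Poisson (conditional negative-binomial) differential
    expression test with Benjamini-Hochberg FDR and fold-change calling;
    tiered one-sample t-tests of iTRAQ protein ratios against assumed
    fold-change nulls; internal-standard metabolite normalization, energy
    panel ratios and two-sample testing; delta-delta-Ct qPCR quantification;
    and Fisher/Wilcoxon functional-category enrichment. A synthetic-data
    generator with known ground truth emulates the two-genotype,
    three-time-point study design for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
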