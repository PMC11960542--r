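Package: moqtl
Title: Multiomic QTL Mapping, Complex-QTL Networks, and GWAS Colocalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for integrating molecular quantitative trait
    loci (QTLs) across multiple molecular phenotypes (gene expression,
    chromatin accessibility, histone acetylation). Implements kinship-aware
    linear mixed model cis-QTL mapping with two-step multiple-testing
    correction, stepwise conditional signal discovery with LD-based
    filtering, construction of complex-QTL modules by community detection on
    shared-signal networks, temporal (early-developmental versus adult)
    classification of eQTLs from local-false-sign-rate matrices,
    approximate-Bayes-factor colocalization with GWAS summary statistics
    including 99% credible sets, prioritization of motif-overlapping
    putative causal variants, and Fisher-exact enrichment analyses. A
    synthetic-data module generates family-structured genotypes with block
    LD, count phenotypes with planted cis effects and confounders, GWAS
    summary statistics, and interval annotations with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    edgeR,
    igraph,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
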