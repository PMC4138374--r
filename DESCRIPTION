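Package: stressclust
Title: Two-Step Model-Based Clustering and Differential Response
    Analysis for Density and Nitrogen Stress Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for four-condition (density x nitrogen)
    stress expression experiments in plants: responsive-gene calling by
    fold-change and Benjamini-Hochberg false-discovery-rate filtering against
    an optimal-condition control, three-way Venn partitioning of responsive
    sets, Gaussian parsimonious clustering models (eigen-decomposed component
    covariances) fitted by EM with BIC model selection, parsimonious Gaussian
    mixture models (mixtures of factor analyzers) fitted by AECM, a two-step
    density-split clustering strategy that flags genes whose nitrogen response
    differs between planting densities, 2^-ddCt relative quantification of
    qPCR data against a reference gene, and internal-standard normalization of
    GC-MS metabolite tables with one-way ANOVA and least-significant-difference
    comparisons. Includes seeded synthetic-data generators for every input type
    so the whole pipeline is testable without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
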