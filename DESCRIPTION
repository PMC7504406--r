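Package: metaboPatterns
Title: Differential Metabolite Pattern Analysis Across Hematopoietic Lineages
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Targeted-metabolomics differential abundance pipeline for
    myeloid differentiation studies. Implements log2 preprocessing with
    below-LOD censoring, per-metabolite group-means linear models with
    empirical-Bayes variance shrinkage and moderated t-statistics,
    a relevance filter (|logFC| > 1, FDR < 0.05) with delta-logFC based
    classification of metabolites into lineage-unique and common sets,
    Fisher's exact overrepresentation testing with Holm adjustment, and a
    synthetic Biocrates-style data generator with planted ground-truth
    effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Metabolomics, DifferentialExpression, Software
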