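Package: TissueSpec
Title: Tissue-Specificity Classification of Multi-Tissue RNA-Seq Compendia
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies every gene of a multi-tissue FPKM expression
    compendium into seven tissue-specificity categories (not detected,
    highly enriched, moderately enriched, group enriched, enhanced,
    expressed in all, mixed) for a chosen target tissue, computes
    tissue-specificity scores and mRNA-pool composition, builds the
    bipartite tissue-sharing network of enriched genes, and integrates
    coded immunohistochemistry annotations to call nephron
    compartment-specific proteins and RNA-protein concordance. Includes a
    synthetic-data generator with planted ground truth so the full
    pipeline is testable without access to external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, Classification, Network
RoxygenNote: 7.3.3
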