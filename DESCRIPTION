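Package: tauatlas
Title: Tissue-Specificity Analysis of Multi-Tissue Expression Atlases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses multi-tissue bulk RNA-seq expression
    atlases. Computes the tau tissue-specificity index, classifies genes
    into Tissue-Specific, Group-Enriched, Expressed-In-All and Mixed
    categories following Human Protein Atlas style rules, performs
    one-vs-all negative-binomial likelihood-ratio differential expression,
    detects weighted co-expression modules with per-tissue activity scores
    and hub genes, and extracts tissue-specific protein-protein interaction
    subnetworks from a scored global interactome. Includes a seeded
    synthetic-atlas generator with planted ground truth for end-to-end
    validation, and a pipeline runner producing a reproducible run report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    withr,
    MASS,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
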