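Package: wpcna
Title: Weighted Protein Co-Expression Network Analysis for Spectral-Count
    Proteomics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovery of trait-associated protein co-expression modules from
    label-free spectral-count proteomics with a two-group (e.g. HOT/COLD
    lesion) design. Implements spectral-count quantification (Rsc log2 fold
    change, NSAF relative abundance, G-statistic test), weighted
    co-expression network construction (soft thresholding, topological
    overlap, average-linkage clustering with a dynamic cut-height ladder),
    module eigenproteins and membership, module-trait correlation,
    hypergeometric over-representation screening of modules against
    trait-unique and upregulated protein groups, hub-protein ranking by
    degree and intramodular connectivity, and a synthetic-data generator
    with planted modules and trait effects for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
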