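Package: hepanet
Title: Weighted Co-Expression Network Hub-Gene Discovery for Hepatocellular Carcinoma
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully offline re-implementation of a weighted
    gene co-expression network (WGCNA-style) hub-gene discovery pipeline for
    tumor/adjacent-normal expression studies: paired-sample correlation
    quality control, coefficient-of-variation seed-gene selection,
    soft-thresholded adjacency and topological overlap, deterministic
    dendrogram module detection with eigengenes and module merging,
    module-trait association, protein-protein interaction neighborhood
    hypergeometric hub screening, clinicopathological association tests,
    Kaplan-Meier/log-rank/Cox survival analysis, and GSEA/ssGSEA-based
    functional and immune-infiltration scoring. Ships a synthetic-data
    generator with planted modules, hubs, and survival effects so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    survival,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
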