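Package: netrewire
Title: Multi-Scale Co-Expression and Network Rewiring Analysis of
    Two-Condition Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative systems-biology toolkit for comparing two disease
    transcriptomes (e.g., type 2 diabetes mellitus versus hypertension) across
    multiple network scales. Provides expression preprocessing (quantile
    normalization, condition-preserving batch adjustment, probe collapsing,
    variance filtering, outlier detection), empirical-Bayes moderated
    differential expression, weighted co-expression network analysis
    (soft-threshold selection by scale-free fit, topological overlap, module
    detection with eigengene merging, module-trait correlation), a per-gene
    differential-connectivity rewiring score with Fisher r-to-z differential
    edges, STRING-style protein-protein interaction analysis (hubs by degree
    and betweenness, greedy-modularity communities), regulon-based
    transcription-factor activity scoring, hypergeometric gene-set
    over-representation, tissue-specificity Z-scores, and a five-layer
    integrative network with GraphML export. A seeded synthetic-data generator
    with planted ground truth (differentially expressed genes, correlated
    modules, condition-specific rewired hubs, active regulons) makes every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
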