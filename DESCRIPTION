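Package: mitolin
Title: Single-Cell Mitochondrial Lineage Tracing and Clonal Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Clonal inference for single-cell deep mitochondrial-DNA mutation
    profiling. Groups aligned mtDNA fragments by endogenous UMIs (cell barcode
    plus fragment endpoints), performs single-molecule consensus error
    correction and multistep variant filtering, and builds heteroplasmy and
    binarized variant-by-cell matrices. Downstream tools cover prior-weighted
    Jaccard distances, TF-IDF/SVD (LSI) embeddings, neighbour-joining
    phylogenies with maximum-likelihood variant-to-branch assignment and
    tree-cut clonal groups, random-walk-with-restart assignment of progeny to
    stem-cell clones on mutual-KNN graphs, clonal output and lineage-bias
    statistics, clonal-diversity and coalescent clade-expansion tests,
    tree-shape fitness proxies, and loss-of-chromosome-Y detection. Includes a
    full generative simulator of clonally structured populations accruing
    heteroplasmic mtDNA mutations, with molecule capture, read-level
    sequencing error and ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    ape,
    irlba,
    RANN,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
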