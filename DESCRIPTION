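Package: floratlas
Title: Probabilistic 3D Gene Expression Atlases from Single-Nucleus
    Transcriptomes and Binary Spatial Reference Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs genome-wide three-dimensional gene expression
    atlases of a plant organ by probabilistically mapping single-nucleus
    RNA-seq transcriptomes onto a 3D spatial reference map that carries
    only binary expression calls for a small set of reference genes. The
    mapping is a fused entropic Gromov-Wasserstein optimal transport
    between kNN-graph geodesic representations of the transcriptomes and
    of the spatial map, with a linear cost on reference-gene profiles
    (Euclidean, Jaccard or Hamming). Includes leave-one-gene-out AUROC
    validation, per-gene predicted-estimation-performance (PEP) scores,
    expression-domain identification by hierarchical clustering,
    localization of external transcriptomic signatures and of snRNA-seq
    clusters onto the map, and a synthetic dome-shaped meristem simulator
    with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mclust,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
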