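Package: mvembed
Title: Multi-View Neighbourhood Embedding and Multi-Objective Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates multiple feature views (e.g. multi-omics assays on a
    shared patient cohort) by combining per-view neighbour probability
    distributions through conflation (the normalized product of densities),
    learning a low-dimensional embedding that minimizes the Kullback-Leibler
    divergence to the unified distribution under a Student-t kernel, and
    clustering the embedding with an archived multi-objective simulated
    annealing algorithm that optimizes the Xie-Beni and PBM validity indices
    with a variable number of clusters. Supports incomplete views (samples
    missing from some assays), averaging-based baseline combiners, a stacked
    denoising autoencoder initializer, external validity metrics (NMI, ARI,
    macro F1, accuracy), signal-to-noise marker scoring, and a synthetic
    multi-view Gaussian-mixture generator for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
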