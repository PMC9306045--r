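Package: ccimpute
Title: Consensus-Clustering Imputation of Dropout Events in scRNA-seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imputes dropout events (technical zeros) in single-cell RNA-seq
    expression matrices using a cell-cell similarity measure derived from
    consensus clustering. Cells are compared with a gene-variance-weighted
    Spearman distance, the distance matrix is PCA-transformed and clustered
    with restarted K-means over a family of principal-component sub-datasets,
    and the resulting consensus matrix drives a weighted vote that separates
    dropouts from biological zeros. Dropouts are then filled with
    consensus-weighted means of similar cells by solving a per-gene linear
    system, leaving all non-zero entries untouched. Also provides a
    Splatter-style negative-binomial count simulator with ground-truth labels
    and dropout masks, and evaluation metrics (adjusted Rand index, average
    silhouette width, zero-change fraction) for benchmarking imputation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    Rtsne,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
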