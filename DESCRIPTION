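Package: rsnsage
Title: Resting-State Network Extraction from ROI Time Series via
    Unsupervised GraphSAGE Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts resting-state networks, in particular the default
    mode network, from region-of-interest (ROI) level resting-state fMRI
    time series. Builds a thresholded group-mean Pearson correlation
    graph over ROIs, learns unsupervised node embeddings with a
    from-scratch GraphSAGE implementation (fixed fan-out neighbour
    sampling, mean or max-pooling aggregation, random-walk positive
    pairs with a negative-sampling loss), reduces the embeddings with
    PCA at a retained-variance target, partitions ROIs with Lloyd
    k-means, and identifies the default mode network cluster by overlap
    with a reference ROI list. A seed-based correlation baseline
    (Fisher z, one-sample group t map, Student-t threshold) and a
    synthetic multi-subject cohort generator with planted network
    structure are included so the whole pipeline is testable without
    external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    mclust,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
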