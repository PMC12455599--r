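Package: svgclust
Title: Spatially Variable Gene Detection, Pattern Clustering, and Spatial
    Domain Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects spatially variable genes (SVGs) in spot-level spatial
    transcriptomics with a Gaussian-process variance-component score test
    over a bank of Gaussian and Cosine kernels, combines per-kernel p-values
    with the Cauchy rule, and controls the false discovery rate with
    Benjamini-Hochberg. Detected SVGs are grouped by spatial pattern via
    covariate-adjusted re-testing against principal components of their
    correlated peers, a weighted gene dependency graph, and Leiden community
    detection. Per-cluster low-dimensional spatial embeddings are aggregated
    for spatial domain detection, with an adjusted-Rand-index and
    percentage-of-abnormal-spots evaluation toolkit and two ground-truth
    simulators.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    data.table,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
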