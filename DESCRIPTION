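Package: divikr
Title: Divisive Intelligent K-Means Segmentation of High-Dimensional Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Divisive, locally feature-adaptive K-means (DiviK) for
    segmenting high-dimensional biological abundance matrices such as mass
    spectrometry imaging (MSI) datasets. Each region of the recursion
    re-optimises its own feature space by Gaussian-mixture decomposition of
    per-feature log abundance statistics, tests region homogeneity with a
    two-trial GAP statistic on subsamples, selects the number of subclusters
    with an approximate (centroid-based) Dunn index, and clusters with
    K-means under correlation or Euclidean distance using a deterministic
    KD-tree percentile seeding. Includes evaluation utilities (label
    normalisation against annotated regions of interest, multi-cluster Dice,
    adjusted Rand, overall-quality scores, rank aggregation), a synthetic
    generator of hierarchically structured MSI-like data, readers and
    writers for the involved tabular and JSON formats, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    data.table,
    mclust,
    optparse,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
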