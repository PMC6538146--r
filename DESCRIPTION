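Package: placemass
Title: Analysis of Phylogenetic Placement Mass Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-analysis toolbox for phylogenetic placement data (jplace
    files). Interprets likelihood weight ratios of placed query sequences as
    point masses on the edges of a fixed reference tree and provides mass
    normalization, branch binning, squashing, and edge imbalances; the
    phylogenetic Kantorovich-Rubinstein (earth mover) distance between
    samples; Squash Clustering and phylogenetic as well as imbalance k-means;
    Edge Dispersion, Edge Correlation and Edge PCA visualizations with
    color-mapped trees; a placement adaptation of the phylogenetic isometric
    log-ratio transform (balances with edge weights); and
    Placement-Factorization, a greedy phylofactorization of placement data
    driven by a generalized-linear-model deviance objective on per-sample
    meta-data. Includes a fully seeded synthetic data generator for trees,
    placement samples and meta-data with planted clade signals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
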