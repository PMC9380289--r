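Package: trajpresence
Title: Statistical Test for the Presence of a Trajectory in a Point Cloud
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies the statistical evidence that a low-dimensional
    point cloud, such as a PCA projection of single-cell RNA-seq data,
    contains a trajectory. The data are partitioned with k-means, a
    Euclidean minimum spanning tree is built on the cluster centers, and
    three tree-shape statistics (the number of degree-one nodes, the
    number of degree-two nodes, and the length in edges of a longest
    path) are compared against permutation null distributions. One-tailed
    empirical p-values are computed for every number of clusters in a
    user-chosen range and summarized by their median per statistic. A
    synthetic-data module generates point clouds with known trajectory
    topology for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
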