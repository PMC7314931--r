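Package: dynfc
Title: Dynamic Functional Connectivity States of the Language Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Sliding-window dynamic functional connectivity (dFC) analysis of
    seed-defined brain networks. Provides seed-based network-node
    identification from 4D fMRI volumes (seed-sphere extraction, Pearson
    correlation maps, Fisher r-to-z, one-sample t maps, family-wise-error
    voxel thresholding, cluster extraction), sliding-window edge
    correlations, k-means clustering of windowed connectivity into recurring
    dFC states with silhouette-based selection of the state count, weighted
    graph-theory topology per window and per state (clustering coefficient,
    characteristic path length, global and local efficiency), and
    nonparametric permutation group inference with max-statistic family-wise
    error control and Cohen's d effect sizes. Includes a synthetic
    multi-subject BOLD generator with planted covariance states, planted
    group effects and a voxel-level phantom so the full pipeline is testable
    end to end without any imaging download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
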