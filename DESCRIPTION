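Package: rootqsm
Title: Quantitative Structure Models and Phenotyping of Tree Root Systems
    from Terrestrial Laser Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs cylinder-based quantitative structure models (QSM)
    of excavated tree root systems from terrestrial-laser-scanning point
    clouds and extracts structural phenotypes: basal root diameters, lateral
    root counts by branching order, total root length, surface area and
    volume. The pipeline reads PLY/XYZ/LAS clouds, denoises and voxel-thins
    them, skeletonizes via a Dijkstra shortest-path tree with geodesic
    binning, fits cylinders by nonlinear least squares, and assigns branching
    orders bottom-up from the root collar. Includes least-squares circle
    fitting for direct diameter measurement, an accuracy-evaluation
    toolkit (R2, RMSE, rRMSE, MAE, recall/precision/F1/accuracy, Pearson r,
    greedy root matching), and a seeded synthetic root-system generator with
    exact cylinder-level ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
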