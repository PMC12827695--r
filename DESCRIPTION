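Package: edgedyn
Title: Edge-Centric Functional Network Dynamics and Group Inference
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for edge-centric analysis of parcellated resting-state
    BOLD time series: edge time series (per-frame co-fluctuation of z-scored
    region pairs), the edge-by-edge co-fluctuation similarity matrix, the
    root-sum-square (RSS) trace with trough/peak event detection (peak
    amplitude and trough-to-trough duration), high- versus low-amplitude
    frame networks over a proportional-sparsity grid, binary graph metrics
    with degree-preserving rewired null models, the network-based statistic
    (NBS) for group-difference subnetworks, ComBat empirical-Bayes multi-site
    harmonization, and effect-size group statistics. Includes a synthetic
    multi-site cohort generator driven by community-structured co-fluctuation
    events for end-to-end testing, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
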