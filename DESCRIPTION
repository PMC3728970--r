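Package: corridorcast
Title: Least-Cost Connectivity Models with GPS-Telemetry Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Least-cost connectivity modelling over categorical land-cover
    rasters and validation of the model predictions against GPS telemetry.
    Implements accumulated-cost (Dijkstra) surfaces on 8-connected grids,
    least-cost paths, habitat networks, buffered path and corridor masks;
    segmentation of GPS fix series into dwell clusters and inter-patch
    movements; land-cover and landscape-feature use statistics including a
    breakpoint (hinge) regression of feature use against distance from
    habitat; and an area-versus-points comparison statistic for ranking
    connectivity models. A synthetic-landscape and biased-random-walk
    simulator provides reproducible end-to-end test data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
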