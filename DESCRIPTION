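Package: depthgait
Title: Markerless Side-View Joint Tracking from Depth Frames for Gait
    Analysis
Version: 0.1.0
Authors@R:
    person("depthgait", "maintainers", email = "depthgait@example.org",
           role = c("aut", "cre"))
Description: Locates and tracks six skeletal joints (head, shoulder, elbow,
    hip, knee, ankle) in side-view depth-frame sequences of a subject
    performing the Get Up and Go Test, using background subtraction,
    silhouette extraction and anthropometric body models calibrated from a
    single front-plane pose.  Includes a synthetic depth-scene generator
    with exact joint ground truth that replaces the depth sensor for
    testing and demonstration, and trajectory-validation metrics against
    marker-based or synthetic reference tracks.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
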