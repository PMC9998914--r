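Package: starpod
Title: Star-Convex Seed Phenotyping for Micro-CT Pod Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automated phenotyping of seeds inside intact seed pods imaged by
    X-ray micro-computed tomography. Seeds are represented as star-convex
    polyhedra described by radial distances along a Fibonacci direction
    lattice; the package provides a training-free star-convex instance
    detector (threshold, distance-transform candidates, non-maximum
    suppression), IoU-threshold evaluation metrics for instance segmentation
    (precision, recall, F1, mean matched/true score, panoptic quality),
    per-seed location and shape measurements (volume, sphericity, solidity,
    extent, axis lengths), lowess-based sorting of seeds into pod valves, and
    a synthetic pod phantom generator with ground-truth labels for
    benchmarking the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    clue,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
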