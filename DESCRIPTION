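Package: climbtech
Title: Climbing Technique Error Detection from 3-D Skeleton Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for bouldering technique assessment from
    video-derived 3-D skeleton keypoint streams. Fits the climbing-wall plane
    from a point cloud (seeded RANSAC plus minimum-area rectangle extraction)
    and re-expresses skeletons in a wall-anchored coordinate system; segments
    per-joint motion with a standard-score envelope; classifies frames into
    the preparation/reaching/stabilization cycle with a finite state machine;
    detects six rule-based technique errors (one referenced against an expert
    climb via dynamic time warping of hip-distance series); and evaluates
    detections against frame-interval ground truth with 1-D
    intersection-over-union precision-recall curves. Includes a scripted
    synthetic climb generator with exact ground-truth phases and injected
    errors so the whole pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
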