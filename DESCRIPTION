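Package: pentrack
Title: Multi-Object Tracking and Evaluation for Animals in Pens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracking-by-detection machinery for top-down video of group-housed
    animals. Implements a three-stage detection-to-track association cascade
    (high-confidence IoU matching, Euclidean re-association of occluded
    targets, and fused IoU plus appearance-embedding matching of low-confidence
    detections), a constant-velocity Kalman motion model over bounding boxes,
    a domain-aware channel-attention feature operator, the standard
    multi-object-tracking evaluation suite (MOTA, MOTP, IDF1, HOTA, MT, ML,
    identity switches), MOTChallenge-format readers and writers, and a
    synthetic pen-scenario simulator with a detector emulator for day- and
    night-like detection-quality regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
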