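Package: reachkin
Title: Kinematic Analysis of Mouse Reach-to-Grasp Behavior from
    Mirror-Based Single-Camera Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for quantifying skilled forelimb movement in the mouse
    single-pellet reach-to-grasp task. Takes two-view 2D keypoint tracks
    (front camera plus tilted-mirror side views, as produced by markerless
    pose trackers), calibrates the views as pinhole cameras by the direct
    linear transform, models mirror views as reflected virtual cameras,
    triangulates 3D paw and pellet trajectories in millimetres, cleans and
    segments them into individual reaches, extracts per-reach kinematic
    scalars (duration, endpoint, path length, speed, acceleration, jerk),
    classifies trial outcomes into six behavioral categories, clusters
    reaches on their kinematic features, and computes session-level learning
    metrics (paw dominance, success rate, shaping and learner criteria,
    learning curves). Includes a synthetic scene generator (minimum-jerk
    reaches, pellet dynamics, mirror geometry, checkerboard calibration
    fixtures, sensor logs) so the whole pipeline is testable without video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    cluster,
    mclust,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
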