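Package: scopeskill
Title: Simulation and Skill Assessment for Oblique-Endoscope Camera Navigation Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico simulator and assessment engine for the 30-degree
    camera navigation exercise used in hysteroscopic dry-lab training.
    Provides remote-center-of-motion (fulcrum) kinematics that recover the
    full endoscope tip pose from a four-encoder passive tracker arm, a
    pinhole camera model for the oblique optic with ellipse-in-ring focus
    scoring, a trial engine implementing the ten-target navigation protocol,
    a synthetic-surgeon cohort generator with logarithmically improving
    performance, per-trial skill metrics (execution time, accuracy,
    orientation error, path length, total rotation, economy-of-movement
    ratios), and the learning-curve statistical battery (trial-subset paired
    t-tests with post-hoc power and sample size, Pearson correlation matrix,
    log-fit learning curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
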