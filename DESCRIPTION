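Package: hpbu
Title: Hierarchical Predictive Belief Update for Handwriting Perception,
    Production, and Sense of Agency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-level active-inference hierarchy (Schema, Sequence,
    Vision, Motor Control) that perceives and produces 2D handwriting
    trajectories.  Belief updates at every level follow a free-energy
    weighted Kalman rule over discrete probability distributions; pen
    trajectories are segmented into surprising stroke events coded in a
    gaze-centred polar frame; production is realised by a damped-spring
    equilibrium-point plant with goal lookahead.  A sense-of-agency
    estimator accumulates the temporal-binding likelihood of the intended
    action sequence through the same Kalman machinery.  Includes a
    parametric single-stroke digit corpus generator and a runner for four
    perception/production scenarios with congruent or substituted visual
    feedback.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
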