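Package: vmadapt
Title: Visuomotor Rotation Adaptation: Simulation, State-Space Modelling
    and Trial-Series Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing visuomotor-rotation adaptation experiments
    that separate within-trial (online-correction) and between-trial
    (plan-update) learning. Provides a seeded synthetic-cohort simulator for
    two joystick tasks (continuous reaching and ballistic curling) under a
    blocked adaptation/de-adaptation schedule with reward, punishment or
    neutral feedback; reach-trajectory kinematics (angular error at peak
    velocity or at a fixed release radius, direction-change counts, control
    time); outlier-robust preprocessing of trial series (extreme-error
    removal, sliding-window Hampel filter, log standardisation to baseline);
    block-wise fitting of a single-rate state-space learning model by bounded
    least squares with multi-start optimisation; and adaptation summaries
    (savings, retention, washout aftereffects, early variability, condition
    contrasts with false-discovery-rate correction, partial correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
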