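Package: rigid4d
Title: Simulation and Analysis of Rigidity Perception in Three and Four
    Spatial Dimensions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying structure-from-motion rigidity perception
    with wireframe cubes and hypercubes (tesseracts). Builds regular and
    irregular d-dimensional hypercube wireframes, animates them with rigid
    plane rotations or non-rigid shear-plus-deformation motion, projects 4D
    trajectories to 3D and 3D scenes to stereoscopic image coordinates,
    assembles two-alternative forced-choice sessions, simulates a
    configurable synthetic observer (choice, reaction time, confidence,
    head-pose traces), and analyses trial logs with per-condition
    summaries, linear mixed-model ANOVA with Satterthwaite denominator
    degrees of freedom, confidence-reaction-time correlation, and
    head-movement statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    withr,
    numDeriv,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
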