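Package: tsmorph
Title: Triceps Surae Morphometry, Achilles Tendon Mechanics, and Gait Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify triceps surae muscle volumes and Achilles
    free-tendon geometry from 3-D label maps, estimate the Achilles tendon
    moment arm about a functional (screw) ankle axis from marker-cluster
    kinematics and tendon edge points, reduce treadmill gait trials to
    per-cycle ankle plantarflexion moments and spatiotemporal parameters
    via sagittal-plane inverse dynamics, and compare young and older
    cohorts with exact Mann-Whitney tests, uncapped Holm step-down
    correction, and allometric scaling regressions. Includes a synthetic
    data generator (voxelized phantoms, range-of-motion trials, gait
    trials, two-group cohorts) with known ground truth so every stage of
    the analysis is verifiable without subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    signal,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
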