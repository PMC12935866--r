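Package: gaittube
Title: Phase-Dependent Gait Tube Analysis of Center-of-Mass Velocity
    Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Continuous, phase-dependent analysis of three-dimensional
    center-of-mass (COM) velocity variability during treadmill walking.
    Builds per-gait-phase 3x3 covariance matrices of stride-to-stride COM
    velocity, derives variability ellipsoids and their volumes, projects
    them onto Frenet-Serret cross-sectional planes to form a "gait tube",
    and compares groups with Wilcoxon rank-sum tests, permutation-based
    one-dimensional statistical parametric mapping over the gait cycle,
    and Fisher r-to-z comparison of correlation coefficients.  Includes a
    seeded synthetic two-group gait-cohort generator (pelvis markers plus
    vertical ground reaction force) so the full pipeline is testable
    without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    signal,
    stats,
    utils,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
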