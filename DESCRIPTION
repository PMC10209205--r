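Package: gaitstab
Title: Outdoor Gait Stability Analysis from Wearable Kinematics and
    Instrumented Insoles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A stride-level pipeline for analysing gait stability from
    wearable-sensor recordings: heel-strike and toe-off event detection
    from insole forces and foot kinematics, jump-based clock
    synchronization, stride segmentation with per-stride anatomical
    coordinate frames and percent-gait normalization, margins of
    stability from the extrapolated centre of mass, local divergence
    exponents by Rosenstein-type delay-embedding, foot-placement
    (stepping-strategy) regressions on the midstance centre-of-mass
    state, ankle/trunk compensation regressions, spatiotemporal gait
    measures with intra-subject variability, nondimensionalization by
    leg length and gravity, and the associated statistical comparisons
    (unpaired t-tests, one-way ANOVA with Holm-Sidak post hoc tests and
    eta-squared effect sizes). Includes a synthetic gait generator with
    known ground-truth controller gains so every analysis stage has a
    recoverable target.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
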