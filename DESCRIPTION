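Package: flickmorph
Title: Morphology and Kinematics of Substrate-Biting Head Flicks in Fishes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking fish control-surface morphology to the kinematics
    of the substrate-biting "head flick". Computes moments of inertia of planar
    silhouettes about vertical (yaw) axes by exact strip decomposition, with an
    independent pixel-integration oracle; simulates latch-released, spring-driven
    head flicks of a hinged two-segment model under constant torque and
    angular-momentum balance, emitting landmark trajectories at video frame
    rates; extracts head angular speed and body angular displacement from
    landmark time series; generates synthetic study datasets (pure-birth
    phylogenies, correlated Ornstein-Uhlenbeck trait evolution, parametric
    silhouettes normalized to a fixed head area); and fits the study's
    statistical layer: ordinary least-squares regressions of kinematics on
    moment of inertia and phylogenetically corrected Pearson correlations among
    control-surface moments of inertia under an Ornstein-Uhlenbeck model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
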