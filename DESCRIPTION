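Package: s100gate
Title: S100A1 Gating Metrics, Umbrella-Sampling Free Energies and
    Calcium-Dependent Target Competition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for the calcium-dependent activation of the
    EF-hand protein S100A1 and its competition with actin for the titin
    PEVK segment.  Provides structural gating metrics computed on
    structures and trajectories (H3/H4 inter-helix opening angle,
    alpha-helicity by Kabsch-Sander hydrogen-bond assignment, residue
    contact maps, RMSF, Shrake-Rupley solvent accessibility, hydrogen-bond
    counts, per-residue interaction-energy decomposition, hierarchical
    clustering on pairwise RMSD); reconstruction of one-dimensional
    potentials of mean force from umbrella-sampling windows by the
    weighted histogram analysis method with Monte-Carlo bootstrap and
    block-averaging/mean-force error estimators; and a multi-state
    mass-action model of competitive S100A1/actin binding of PEVK with
    dissociation-constant calibration against experiment and
    post-translational-modification predictions.  Includes seeded
    synthetic-data generators (Metropolis umbrella sampling from known
    potentials, ideal backbone builders, noisy dose-response curves) so
    every stage is testable against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
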