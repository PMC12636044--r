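Package: memhairpin
Title: Membrane-Binding Analysis of Helical-Hairpin Peptide Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trajectory analysis for peptide-membrane binding studies of
    ESCRT-III-type helical hairpins: heavy-atom contact counting with
    periodic minimum-image cell lists, sustained-contact binding and
    unbinding state detection with first-binding-time distributions,
    per-residue fractional occupancy with bias-corrected accelerated
    (BCa) bootstrap confidence intervals, essential-dynamics PCA of
    fitted backbone coordinates, Kabsch-Sander alpha-helix assignment,
    Shrake-Rupley solvent-accessible surface area, Laurdan generalized
    polarization and Hill-equation binding-curve fitting, and
    surface-coverage arithmetic including a random-sequential-adsorption
    simulator. Ships a synthetic-data module (ideal helices, helical
    hairpins, lipid slabs, Brownian binding trajectories, two-state
    contact series, noisy binding curves) so every stage is testable
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    minpack.lm,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    boot,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
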