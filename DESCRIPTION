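Package: lipidmix
Title: Contact-Fraction and Landscape Analysis of Phase-Separated
    Coarse-Grained Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Trajectory analysis for coarse-grained bilayer simulations of
    liquid-ordered / liquid-disordered phase separation in ternary lipid
    mixtures (DPPC, DLiPC, cholesterol) with hydrophobic solutes. Reads
    GROMOS-87 (.gro) coordinate frames, computes minimum-image contact
    statistics (the DLiPC-DPPC mixing fraction f_mix and solute- and
    cholesterol-DLiPC partitioning fractions) with block-averaged errors,
    builds 50x50 planar density, density-fraction and thickness landscapes,
    locates domain interfaces and estimates per-phase thickness and thickness
    mismatch, and traces the (solute partitioning, lipid mixing) mechanism
    phase plane. A deterministic striped-membrane generator with known ground
    truth (composition, mixing degree, solute placement, per-phase thickness)
    stands in for microsecond molecular-dynamics trajectories so every
    analysis stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
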