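Package: pkashift
Title: Charge Regulation and Apparent pKa Shifts in Amyloid Fibril Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies proton uptake and apparent pKa shifts when a charged,
    intrinsically disordered protein assembles into amyloid fibrils, using
    alpha-synuclein as the model system. Implements a closed-system
    proton-balance inference that converts a measured pH change during
    fibrillation into an apparent average pKa of the acidic groups in the
    fibrillar state, together with Henderson-Hasselbalch titration utilities
    (protonation degree, net charge, proton-binding capacitance), a
    constant-pH coarse-grained Metropolis Monte Carlo simulator (one bead per
    residue, screened Coulomb plus Lennard-Jones interactions, rigid fibril
    core with flexible termini), and a synthetic-data generator for
    electrode-noise parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    bio3d
Config/testthat/edition: 3
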