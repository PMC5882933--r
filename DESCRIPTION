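Package: fragcharge
Title: Fragment-Based ESP Charges and Continuum Solvation for Proteins
Version: 0.1.0
Authors@R: person("fragcharge", "developers", role = c("aut", "cre"),
    email = "fragcharge@example.org")
Description: Electrostatically embedded fragmentation of polypeptides with
    conjugate caps, ESP/RESP atomic-charge fitting of capped fragments with
    link-atom restraints, assembly of per-atom protein charges with concap
    and two-body corrections, molecular electrostatic potential evaluation
    and comparison on shell grids, and electrostatic solvation energies from
    a finite-difference linearized Poisson-Boltzmann solver coupled
    self-consistently to the charge model. Includes an ideal-geometry
    peptide fixture generator and a deterministic mock quantum backend so
    the whole pipeline runs without external engines.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
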