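Package: tcrtails
Title: Coarse-Grained Simulation of Disordered T Cell Receptor Cytoplasmic Tails
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Residue-scale simulation of the intrinsically disordered
    cytoplasmic chains of the T cell receptor. Freely jointed chains are
    sampled from the canonical ensemble by adaptive Metropolis-Hastings Monte
    Carlo under membrane and ligand steric constraints; per-site occlusion
    probabilities are converted to relative ligand binding rates; Gillespie
    simulation of multisite (de)phosphorylation turns rate tables into
    sequence preferences, dose-response curves and Hill coefficients. Includes
    electrostatic membrane-association potentials with calibration routines,
    multi-ligand simultaneous-binding experiments on the six-chain receptor,
    a packing-feasibility search, and an integrative ODE model of
    phosphorylation and ZAP70 loading.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    deSolve
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
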