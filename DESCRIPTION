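Package: ladderNMR
Title: Spin Dynamics and Relaxation Analysis of Amide Side-Chain Ladders by Fast MAS NMR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse asparagine/glutamine side-chain ladders in amyloid
    fibrils by fast magic-angle-spinning (MAS) solid-state NMR. Builds small
    proton/nitrogen dipolar-coupling networks from PDB coordinates or idealized
    synthetic ladder geometries, propagates the rotor-modulated secular spin
    Hamiltonian with powder averaging to simulate 1D spectra and
    rotor-synchronized spin-echo decays (coherent homogeneous linewidths),
    computes analytic and density-matrix refocused-INEPT editing efficiencies
    for NH versus NH2 groups, fits mono-exponential relaxation decays with
    residual-resampling bootstrap errors, and applies transparent rule-based
    criteria to call rigid hydrogen-bonded ladders versus flexible side-chains
    from per-residue observables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    minpack.lm,
    jsonlite,
    yaml,
    tibble,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
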