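Package: wepath
Title: Weighted-Ensemble Path Sampling, Binding Kinetics, and
    Transition-Path Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the weighted-ensemble (WE) rare-event sampling
    algorithm for stochastic dynamics: binned trajectory splitting and
    merging with exact statistical-weight bookkeeping, equilibrium and
    recycling (steady-state) modes, mid-run bin-scheme switching, and
    history-labeled steady-state decomposition of an equilibrium ensemble
    into binding and unbinding components.  Ships a Brownian-dynamics toy
    model of bimolecular association on a patchy-sphere pair with a
    metastable encounter-complex intermediate, closed-form and brute-force
    mean-first-passage-time oracles, progress-coordinate machinery (minimum
    separation and anchor-point binding RMSD after Kabsch superposition),
    conditional-flux rate constants (association k1/kon, unimolecular k2,
    productive-collision percentage), Monte Carlo blocked-bootstrap
    confidence intervals with autocorrelation-based block lengths, and
    transition-path-ensemble analyses: event durations, weighted contact
    probabilities, histogram conformational entropy, k-centers
    conformation-space networks with the Canberra metric, and spherical
    ligand entry-point maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
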