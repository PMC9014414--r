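Package: torusves
Title: Variationally Enhanced Sampling and Free-Energy Analysis on Periodic
    Dihedral Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying activated conformational transitions of a
    chromophore-protein photoswitch surrogate on a two-dimensional torus of
    dihedral collective variables. Provides analytic periodic model
    potentials with exact gradients, overdamped Langevin dynamics,
    variationally enhanced sampling with a Fourier-series bias optimized by
    averaged stochastic gradient descent towards a uniform target
    distribution, free-energy landscape reconstruction by umbrella
    reweighting, metastable-state extraction by density-based clustering on
    the torus, Kullback-Leibler convergence diagnostics, barrier-to-timescale
    conversions, and trajectory-level structural observables (RMSD, RMSF,
    hydrogen bonds, residue contacts) on toy protein trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
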