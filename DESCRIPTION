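Package: cgmelt
Title: Bottom-Up Coarse-Graining of Linear Polymer Melts by Iterative
    Boltzmann Inversion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Systematic bottom-up coarse-graining of linear polymer melts at
    one bead per monomer. Maps fine-grained trajectories to monomer centers of
    mass, builds the four target distributions (bond length, bending angle,
    dihedral, monomeric radial distribution function with bonded exclusions),
    derives tabulated effective potentials by direct and Iterative Boltzmann
    Inversion with an embedded tabulated-potential molecular-dynamics engine
    (Langevin thermostat, weak-coupling barostat, periodic boundaries), and
    provides the structural and dynamical validation suite for melts of
    poly(epsilon-caprolactone)-like chains: internal distances, characteristic
    ratio, gyration-tensor shape analysis, single-chain form factor,
    end-to-end orientational relaxation with stretched-exponential fits,
    center-of-mass diffusion, time-scaling factors, packing length and
    entanglement estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    ggplot2,
    generics,
    minpack.lm,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pracma
Config/testthat/edition: 3
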