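Package: shapeEnsemble
Title: SHAPE-Directed Modeling of RNA Secondary Structure Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the equilibrium ensemble of RNA secondary structures
    from a single sequence and per-nucleotide SHAPE reactivities. A
    thermodynamic Boltzmann ensemble is refined with per-nucleotide
    pseudo-free-energy restraints derived from the mismatch between
    reactivities estimated from the ensemble and the measured profile;
    the restrained ensemble is stochastically sampled, clustered by
    base-pair distance with automatic selection of the number of
    conformations (Calinski-Harabasz index), and summarised as centroid
    structures with populations, per-cluster pair probabilities and the
    Shannon entropy of base pairing. Includes a forward simulator of
    population-weighted SHAPE profiles for mixtures of known structures,
    accuracy metrics with slipped-pair tolerance, and grid-search
    calibration of the restraint parameters with jackknife validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    cluster,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
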