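Package: icneuro
Title: Quantitative Characterization of Inferior Colliculus Neuron Classes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for characterizing neuron classes in the mouse
    inferior colliculus from slice physiology and quantitative anatomy:
    extraction of intrinsic membrane properties and firing-pattern
    classification from current-clamp step families, PCA-based dendritic
    morphometry of SWC reconstructions (stellate versus disc-shaped
    classification, laminar orientation and spread), design-based
    stereological estimation of labeled-neuron fractions with the optical
    fractionator, topographic plane fits of physiology against position in
    the central nucleus, and kinetic analysis of optogenetically evoked
    postsynaptic potentials including feedforward-inhibition quantification.
    A seedable synthetic-data generator produces current-clamp sweeps, SWC
    arbors, labeled 3D point fields and PSP sweep sets with the statistical
    structure the analyses assume, for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    Rcpp,
    minpack.lm,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
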