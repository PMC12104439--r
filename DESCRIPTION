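Package: gmmrefine
Title: CryoEM Model Refinement with Gaussian Mixtures and Differentiable
    Stereochemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Refines atomic models against cryo-electron microscopy density
    maps by representing the model as a Gaussian mixture (one isotropic
    Gaussian per non-hydrogen atom), scoring map-model agreement with the
    Fourier ring correlation of 2D projections, and scoring stereochemistry
    with differentiable re-formulations of the standard validation metrics
    (bond lengths and angles, planarity, Ramachandran, sidechain rotamers,
    clashes, RNA backbone suites). Small hierarchical neural decoders drive
    a multi-step refinement of a single model against one map, or produce a
    continuous series of geometrically valid models across a conformational
    latent space from the output of heterogeneity analysis. Includes a
    synthetic-fixture generator (toy polypeptides and polynucleotides,
    simulated maps, hinge-motion map series) so the whole pipeline can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
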