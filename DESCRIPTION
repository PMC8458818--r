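Package: perfdens
Title: Conditional Performance-Outcome Densities from Wearable-Derived
    Physiological States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds complete conditional probability densities for human
    performance outcomes (reaction time, executive-function error rate,
    perceptuo-motor error rate) given three physiological predictor states
    (stress, sleep duration, physical exertion).  Marginal densities are
    estimated by pooling per-source kernel density estimates; heterogeneous
    stress measures (cortisol, alpha amylase, heart rate, subjective
    ratings) are fused onto one latent scale through per-source affine maps
    and a shared Gaussian mixture fitted by joint maximum likelihood; and a
    sparse four-dimensional joint density is constructed on a lattice of
    isotropic Gaussian basis functions by an iteratively reweighted
    adaptive LASSO under probability-simplex constraints, with literature
    effect sizes entering as moment constraints.  Conditional outcome
    densities and their summaries (mean, mode, percentiles, central
    intervals, skew, kurtosis) are available in closed form from the fitted
    joint model.  A seeded synthetic-fixture generator supplies
    multi-source inputs with known latent structure so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
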