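Package: chromsol
Title: Differentiable Solver-in-the-Loop Hybrid Modeling of Gradient-Elution Chromatography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation of reversed-phase gradient-elution
    chromatography (equilibrium-dispersive column model with a simplified
    stoichiometric displacement isotherm, discretized by a nodal discontinuous
    Galerkin method and integrated with fixed-step BDF), made differentiable
    end-to-end so that a small node-wise neural network correcting the
    adsorption rates inside the time-stepping loop can be trained by
    backpropagation on fractionated chromatograms. Includes mechanistic
    parameter calibration, hyperparameter grid search, and a synthetic
    six-experiment gradient-elution benchmark with fraction-averaged sampling
    and measurement noise for few-shot training and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
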