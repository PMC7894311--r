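Package: c3ensemble
Title: Multi-Hypothesis C3 Photosynthesis Model Ensemble, Sensitivity
    Analysis and A-Ci Curve Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A 12-member ensemble of enzyme-kinetic C3 photosynthesis models
    built from alternative hypotheses for electron transport, triose
    phosphate use (TPU) limitation and limiting-rate selection (strict
    minimum versus non-rectangular-hyperbola quadratic smoothing), coupled
    to the Medlyn unified stomatal conductance model. Provides
    variance-based process-level and parameter-level (Saltelli first-order)
    sensitivity analysis over the ensemble, closed-form analysis of the
    assimilation reduction imposed by quadratic smoothing, generation of
    synthetic high-resolution A-Ci curves, and Bayesian estimation of
    V_cmax, J_max and the co-limitation smoothing parameter theta_cj from
    A-Ci curves by differential-evolution adaptive Metropolis (DREAM) MCMC
    with Gelman-Rubin convergence diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
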