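Package: qetmdd
Title: Quasi-Equilibrium Target-Mediated Drug Disposition Modelling for a
    VAP-1 Inhibitor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and nonlinear mixed-effects estimation tools for a
    population pharmacokinetic-pharmacodynamic model of the oral VAP-1
    (vascular adhesion protein-1) inhibitor ASP8232.  The model couples a
    three-compartment disposition system with quasi-equilibrium binding of
    drug to soluble and membrane-bound target pools (a multiple-target
    TMDD model), covariate effects of renal function and sex, log-normal
    inter-individual variability with a full covariance block, and additive
    residual error on the log scale.  The package generates virtual
    cohorts and NONMEM-style longitudinal datasets, integrates individual
    concentration-time profiles with a compiled ODE right-hand side,
    derives steady-state exposure and time-to-steady-state metrics, fits
    the model by MAP empirical-Bayes and Laplace-approximate marginal
    likelihood, performs stepwise covariate selection, and produces visual
    predictive check percentile bands and concentration-effect summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    tibble,
    tidyr,
    rlang,
    ggplot2,
    stats,
    utils,
    MASS,
    yaml,
    generics
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
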