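Package: ramerpk
Title: Exposure-Response Analysis Pipeline for Ramucirumab with a
    Time-Varying-Clearance Population PK Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for trough-exposure-based exposure-response analysis of an
    intravenously infused monoclonal antibody dosed by body weight. Implements
    a two-compartment infusion pharmacokinetic model whose clearance declines
    over time following a sigmoidal Emax function, forward simulation and
    trough prediction (Cmin after the first dose and at steady state),
    empirical-Bayes estimation of individual random effects from sparse
    sampling, a virtual-trial generator (covariates, dose modifications,
    protocol-sparse sampling, progression-free survival and adverse-event
    outcomes with configurable exposure dependence), exposure quartile
    summaries, exposure-efficacy analysis (Kaplan-Meier and Cox models by
    quartile, stepwise covariate selection, Mahalanobis caliper matched
    case-control analysis), and exposure-safety analysis (incidence tables,
    proportional-odds models for graded toxicities, relative dose intensity).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    survival,
    MASS,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
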