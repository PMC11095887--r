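Package: mmstate
Title: Multi-State Genomic Risk Modelling for Newly Diagnosed Multiple Myeloma
Version: 0.1.0
Authors@R: person("mmstate", "maintainers", email = "maintainers@mmstate.org",
    role = c("aut", "cre"))
Description: Derives model-ready prognostic genomic features from driver-level
    calls in newly diagnosed multiple myeloma (copy-number classes, hyperdiploidy,
    mono-/biallelic tumour-suppressor status, hyper-APOBEC), assigns patients to
    twelve genomic groups via an ordered rule set, computes ISS/R-ISS/R2-ISS
    comparator staging, fits a two-phase six-state multi-state survival model with
    flexible per-transition hazards (Cox partial likelihood with optional time-bin
    interactions and a small hidden layer) and time-dependent treatment covariates,
    predicts individualized state-occupation trajectories and 5-year
    progression-free survival across enumerated treatment courses, computes the
    within-patient treatment-variance statistic, and evaluates models with
    Harrell's concordance index under stratified repeated cross-validation.
    Includes a synthetic cohort generator emulating the assumed statistical
    structure for testing end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
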