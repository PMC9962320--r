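Package: mtxppk
Title: External Evaluation of Population Pharmacokinetic Models of
    High-Dose Methotrexate in Pediatric ALL
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for external validation of published population
    pharmacokinetic (PopPK) models of high-dose methotrexate (HD-MTX) in
    children with acute lymphoblastic leukemia.  Provides a declarative
    catalog of six published two- and three-compartment models with their
    covariate relations and variability terms, an exact piecewise
    matrix-exponential solver for infusion regimens, maximum a posteriori
    (MAP) Bayesian estimation of individual random effects (empirical
    Bayes, NONMEM posthoc semantics), prediction-error statistics
    (median PE, MPE, relative RMSE) with bias and precision acceptance
    rules, Bland-Altman summaries, a virtual therapeutic-drug-monitoring
    cohort simulator, and a flat-file dataset dialect plus a small
    command-line interface tying the pipeline together.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
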