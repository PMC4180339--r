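Package: grmcat
Title: Graded Response Model Calibration and Adaptive Testing Simulation
    for Ordinal Clinical Scales
Version: 0.1.0
Authors@R:
    person("PITSTOP", "Psychometrics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A five-step psychometric pipeline for short ordinal clinical
    questionnaires: classical descriptives and reliability, item response
    theory assumption screening (principal components, one-factor
    confirmatory factor analysis, local independence, Mokken scalability),
    graded response model calibration by marginal maximum likelihood,
    differential item functioning screening via cumulative-logit models
    with McFadden pseudo R-squared effect sizes, and a post-hoc computer
    adaptive testing simulation with maximum-Fisher-information item
    selection and confidence-interval classification stopping rules.
    Ships the 19-item suicide-ideation item bank used throughout the
    documentation, and a graded-response-consistent synthetic cohort
    generator with optional injected differential item functioning.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    statmod
Suggests:
    testthat (>= 3.0.0),
    numDeriv
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
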