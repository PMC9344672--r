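Package: pmrelapse
Title: Relapse Adjudication, Agreement and Prediction Modelling for
    Polymyalgia Rheumatica Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying relapse in polymyalgia rheumatica (PMR)
    cohorts treated with tapering oral glucocorticoids. Implements
    rule-based adjudication of relapse from longitudinal visit records
    under two criteria (rheumatologist judgement and treatment
    intensification, each with a no-relapse-at-previous-visit debounce),
    visit- and patient-level agreement statistics (percent agreement with
    Wilson intervals, Cohen's kappa with an asymptotic standard error),
    incidence rates per patient-year and cumulative incidence at fixed
    horizons, univariable logistic and Poisson association screening for
    baseline predictors, and development plus internal validation of a
    multivariable prediction model via chained-equations multiple
    imputation, across-imputation backward elimination, Rubin pooling and
    bootstrap optimism-corrected discrimination. A configurable synthetic
    cohort generator with covariate-dependent relapse hazard makes the
    whole pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nnet,
    stats,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
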