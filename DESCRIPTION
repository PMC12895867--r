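Package: faerstee
Title: Pharmacovigilance Analysis of Thromboembolic Events in FAERS-Style Spontaneous Report Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for disproportionality analysis of thromboembolic
    events under antiangiogenic monoclonal antibodies in spontaneous
    adverse-event report data distributed in the FAERS quarterly ASCII dialect.
    Provides ingestion and FDA-rule deduplication of report archives, Preferred
    Term event classification against a configurable dictionary, cohort
    construction with route/reporter/role filters, reporting odds ratio and
    Bayesian information component signal statistics with dual thresholds,
    time-to-onset summaries with nonparametric comparisons, a multivariable
    logistic model of fatal outcome, and a synthetic FAERS archive generator
    with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
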