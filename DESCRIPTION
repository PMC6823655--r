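Package: bpscore
Title: Biopsychosocial Complexity Scoring from Linked Multi-Source Client Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes real-time, person-oriented biopsychosocial complexity
    profiles for community-health-center clients from linked multi-source
    records (primary-care and community mental-health EMR extracts, emergency
    department and acute-care data marts). Nine domain scores (attachment,
    service density, social/environmental, psychosocial, relationships,
    activities of daily living, medical complexity, acute utilization, risk of
    harm) are derived from encounters, HoNOS assessments, problem lists,
    vitals, CTAS-graded emergency visits, admissions, PHQ-9 results and
    administrative flags, then combined into weighted and unweighted composite
    complexity scores by the root-sum-squared method. Includes population-level
    reporting, survey-based domain weighting, a synthetic multi-source cohort
    generator for testing without patient data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
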