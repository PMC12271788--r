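Package: mashcohort
Title: Rule-Based Detection of Steatohepatitis in Clinical Notes and EHR
    Cohort Construction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Identifies metabolic dysfunction-associated steatohepatitis
    (MASH, formerly NASH) diagnoses in free-text specialist notes with a
    keyword lexicon and NegEx-style negation rules scoped to the Assessment
    & Plan section, and turns the note-level calls plus a structured patient
    registry into an analysis cohort: index dates, exclusion rules,
    cirrhosis subcohorts, baseline covariates (BMI categories, MELD 3.0),
    competing-risk time-to-event tables, and person-year incidence rates.
    Includes a chart-review validation workflow (dual review, adjudication,
    confusion-matrix metrics) and a synthetic note and registry generator
    with known ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
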