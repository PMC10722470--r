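Package: sentryr
Title: Rule-Based Computational Phenotype Surveillance for Clinical Encounter Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open, testable implementation of a rule-based electronic
    health record (EHR) surveillance engine for human-trafficking risk
    detection. Temporally versioned computational phenotypes (keyword
    patterns with SQL-LIKE wildcards and ICD-10-CM codes) are applied to
    micro-batched encounter streams; matches raise alerts with exact
    evidence spans, previously flagged patients are re-surfaced on every
    subsequent visit, and a capacity-limited High-Risk Patient Navigator
    model screens the alert queue. Aggregation utilities summarize the
    alert -> screened -> "highly suspicious" funnel by period and month,
    and a seeded synthetic-cohort generator with planted triggers and
    ground-truth labels makes the whole pipeline testable without any
    real patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lubridate,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
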