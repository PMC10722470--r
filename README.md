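# sentryr

Rule-based computational-phenotype surveillance for clinical encounter
streams, aimed at detecting patients at risk of human trafficking.

Healthcare visits are one of the few reliable touchpoints with trafficked
persons, but the signals — scattered keywords in social-work notes,
trafficking-specific ICD-10-CM codes, repeated emergency-department visits —
are easy to miss at the level of a single encounter. sentryr is an open,
testable implementation of the "sentry" pattern used in hospital anti-
trafficking programs: a temporally versioned keyword/code phenotype is
applied to micro-batched encounter data, matches raise alerts with exact
evidence, previously flagged patients are re-surfaced on every subsequent
visit so one High-Risk Patient Navigator (HRPN) can build rapport over
time, and the alert → screened → "highly suspicious" funnel is summarized
per reporting period. A seeded synthetic-cohort generator with planted
triggers and ground-truth labels makes the whole pipeline testable without
any real patient data.

## The core model

* **Phenotype**: keyword patterns matched against whole word tokens
  (lowercased, split on non-alphanumeric boundaries), with `%` as a
  SQL-LIKE wildcard for any character run within a token — `traffic%`
  matches *trafficking*; `abuse` does **not** match *abusive*; `anal` does
  **not** fire inside *analysis*. ICD-10-CM patterns compare in normalized
  form with prefix matching (`T74.21` matches a recorded `T74.21XA`).
  Patterns carry sex scopes (a male-specific list exists) and effective
  dates; `assemble_ruleset_as_of()` reconstructs the vocabulary in force on
  any date from the packaged quarterly history.
* **Sentry**: one alert per matching encounter, aggregating every
  (pattern, source) hit with character spans; deterministic alert ids;
  optional ED-utilization rule (default ≥ 4 ED visits in 90 days) and
  longitudinal re-alerting of previously flagged patients.
* **Navigator model**: monthly review capacity, earliest-first queue,
  unreviewed alerts expire at month end; the subjective "highly
  suspicious" call is a seeded Bernoulli draw; repeat alerts keep the
  patient's first navigator.
* **Funnel**: percentages recomputed from integer counts (never averaged),
  rounded half-up to 2 decimals; `baseline_comparison()` annualizes
  detections against a pre-program baseline.

## Worked example

```r
library(sentryr)

versions <- load_ruleset_config(default_ruleset_path())
assemble_ruleset_as_of(versions, "2020-06-30")
#> <sentry_ruleset> as of 2020-06-30: 61 keyword pattern(s), 26 code pattern(s),
#>   code descriptions matched as phrases

enc <- encounter_tbl(
  encounter_id = "E1", patient_id = "P1",
  start_time = "2020-06-30T11:50:00Z", facility_id = "H1",
  encounter_type = "ED", sex = "female", age_years = 24,
  notes = list(note_document(
    "N1", "social_work", "2020-06-30T11:55:00Z",
    "Pt discloses forced labor situation; psych consult placed"
  )),
  diagnoses = list(diagnosis_code(
    "T74.21XA", "Adult sexual abuse, confirmed, initial encounter",
    "2020-06-30T11:58:00Z"
  ))
)
res <- run_batch(enc, versions, batch_time = "2020-06-30T12:00:00Z")
res$alerts$evidence[[1]]
#>   pattern_raw  source                source_id span_start span_end matched_text
#> 1 force%       note_text             N1                13       19 forced
#> 2 forced labor note_text             N1                13       25 forced labor
#> 3 psych%       note_text             N1                37       42 psych
#> 4 T74.21       diagnosis_code        T74.21XA          NA       NA T74.21XA
#> 5 T74.21       diagnosis_description T74.21XA           0       29 Adult sexual...
```

One encounter, one alert: the note fired three keyword patterns (with the
0-based character spans of each match), and the recorded code `T74.21XA`
matched the `T74.21` pattern both as a code prefix and through its
description text. The published period funnel is pure integer arithmetic:

```r
funnel_from_counts(
  c("Sep-Dec 2019", "2020", "Jan-Jul 2021"),
  n_alerts     = c(276, 838, 649),
  n_screened   = c(94, 325, 342),
  n_suspicious = c(30, 71, 83)
)
#>   period_label n_alerts n_screened pct_screened n_suspicious pct_screened_in
#> 1 Sep-Dec 2019      276         94        34.06           30           31.91
#> 2         2020      838        325        38.78           71           21.85
#> 3 Jan-Jul 2021      649        342        52.70           83           24.27
#> 4        Total     1763        761        43.17          184           24.18

baseline_comparison(184, 10, 23)
#> [1] 9.6
```

So 43.17% of all alerts were screened, 24.18% of screened alerts were
judged highly suspicious, and the annualized yield (96/year) is 9.6× the
pre-program baseline of 10 possible cases/year.

A full synthetic pipeline — generate, scan, screen, summarize — is wired
through the `exec/sentry` command-line tool (`sentry gen | scan | retro |
simulate | summarize | ruleset diff`).

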