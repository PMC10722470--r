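---
title: "Rule-based EHR phenotype surveillance: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based EHR phenotype surveillance: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sentryr)
```

## The surveillance model

sentryr implements an always-on, rule-based surveillance loop for detecting
patients at risk of human trafficking from routine electronic health record
(EHR) data. The pipeline has four stages:

1. **Computational phenotype.** A versioned set of keyword patterns and
   ICD-10-CM codes. The vocabulary evolves quarterly; the package replays
   that history so any date's active ruleset can be reconstructed.
2. **Sentry.** Encounters arrive in micro-batches (the operational cadence
   is 15 minutes, four deliveries per hour). Each encounter is scanned
   against the ruleset in force on the batch date; any hit raises one alert
   carrying the full evidence (pattern, source, character span).
3. **Navigator screening.** A High-Risk Patient Navigator (HRPN) reviews
   the alert queue under a monthly capacity budget and labels reviewed
   cases "highly suspicious" or not.
4. **Funnel reporting.** Alerts → screened → highly-suspicious counts and
   percentages per reporting period and per month.

Because the underlying clinical data are confidential, the package ships a
seeded synthetic-cohort generator that plants triggers from the active
ruleset into an otherwise benign encounter stream, with ground-truth
labels. Every stage is testable against that generator.

## Keyword matching semantics

Matching is **lexical only** — no stemming, negation detection, or
statistical NLP. The matching unit is the word *token*: text is lowercased
and split on non-alphanumeric boundaries, and a pattern matches only whole
tokens. The vocabulary itself forces this choice: it lists *abuse* and
*abusive* as separate entries, and a substring semantics would make *anal*
fire inside "analysis".

```{r tokens}
keyword_matches(compile_keyword("abuse"), "abusive partner")   # FALSE
keyword_matches(compile_keyword("anal"), "analysis of labs")   # FALSE
keyword_matches(compile_keyword("traffic%"), "labor trafficking")
```

`%` is a SQL-LIKE wildcard for any (possibly empty) character run **within
one token** (`traffic%` → "traffic", "trafficking", "trafficked"). There is
no single-character wildcard; none appears in the source vocabulary. A
pattern consisting only of `%` is rejected at compile time — it would match
everything. Multi-word patterns match consecutive tokens, and hyphens act
as token separators, so `trans-sexual` compiles to a bigram and matches
both "trans sexual" and "trans-sexual" but not "transsexual" (which is its
own entry). Matching is case-insensitive throughout.

The compiled matcher has a fast path (hashed lookup for single-token
literals); a property test checks it against an independent brute-force
character-level expansion of the wildcard on thousands of random
pattern/token pairs.

## The versioned ruleset

`load_ruleset_config()` reads a YAML history of dated versions, each adding
or removing keyword and code patterns; `assemble_ruleset_as_of(versions,
date)` replays all versions with `effective_from <= date` (inclusive
boundary: a version is active on its own effective date). The packaged
default config transcribes the published quarterly history. Decisions taken
where the source table is ambiguous:

* Entries dated only by quarter take the quarter's first day; the one entry
  carrying a printed mid-quarter date (Z91.41, added 2019-07-22) keeps it.
* *Rapped (sp)* is stored as the literal misspelling trap `rapped`; "(sp)"
  is an annotation, not match text.
* Duplicate listings (Z91.42 appears four times) collapse silently; the
  count of collapsed duplicates is kept on the assembled ruleset as a
  validation attribute.
* **Sex scoping.** The male-specific list adds `penis` and `testic%` as
  `male_only` and subtracts phrases nonspecific for males. Since *black
  eye* is described as subtracted but never printed as an addition, the
  config adds it with the 2019 Q3 general vocabulary and re-scopes it to
  `female_only` in 2020 Q1, which keeps every removal expressible against
  an active pattern. Patients of unknown sex receive the union of all
  scopes — the conservative choice for a sensitivity-first screen.
* The female-specific list was never published; the general list is scoped
  `any`.
* The late-2019 "ICD-10 searches simplified to key phrase" change is
  modeled as a dated flag (`match_code_descriptions_from`): from that date
  the code descriptions are also evaluated as keyword phrases against
  diagnosis description text. The mechanics were not published; the flag
  keeps both behaviors testable.

Diagnosis codes compare in normalized form (uppercase, dot and whitespace
stripped) and default to **prefix** matching, so pattern `T74.21` matches a
recorded `T74.21XA` encounter extension.

## Sentry behavior

* **One alert per encounter**, aggregating all evidence — the reported
  quantities count potential cases, not pattern hits. Alert ids are FNV-1a
  hashes of (encounter id, batch time), so runs are reproducible.
* **Longitudinal re-alerting**: every subsequent visit of a previously
  alerted patient raises an alert (evidence tagged
  `longitudinal_followup`), supporting consistent contact with the same
  navigator. Disable with `sentry_config(longitudinal_realert = FALSE)`.
* **ED utilization**: increased emergency-department utilization is part
  of the phenotype but no threshold was published. The default — at least
  4 ED encounters within 90 days — is an artifact decision, exposed as
  `sentry_config(utilization_threshold, utilization_window_days)`.
* **Late-arriving encounters** are scanned with the *current* batch's
  ruleset (a live sentry cannot travel back); `retrospective_scan()`
  exists for as-of-date analyses and re-runs an archive chronologically
  under one fixed ruleset, reporting per-pattern hit counts and, when
  known-case labels are supplied, sensitivity. With no labels, sensitivity
  is absent, never 0.
* Re-running a batch is idempotent: encounters already alerted in the
  history are skipped.

## Navigator screening model

Within each calendar month alerts are reviewed earliest-fired-first until
the monthly capacity is exhausted; the rest **expire at month end** and are
never back-filled (the period screening fractions vary widely, implying no
back-fill happened in practice). The highly-suspicious determination was
explicitly a subjective navigator judgment, so it is modeled as a
Bernoulli(`suspicion_rate`) draw from a seeded RNG rather than a rule.
Repeat alerts are routed to the navigator who first reviewed the patient;
affinity is strict — if that navigator has no capacity left, the alert
expires rather than switching reviewers, matching the rapport-building
intent of the program. `contact_made` is an independent Bernoulli(0.5)
draw recorded for completeness; it feeds no funnel metric.

## Funnel arithmetic

Percentages are always recomputed from integer counts — the Total row uses
the summed integers, never the mean of period percentages — and rounded
half-up to 2 decimals, matching the published table's precision:

```{r funnel}
funnel_from_counts(
  c("Sep-Dec 2019", "2020", "Jan-Jul 2021"),
  n_alerts = c(276, 838, 649),
  n_screened = c(94, 325, 342),
  n_suspicious = c(30, 71, 83)
)
```

Zero denominators yield `NA` percentages rather than 0. One documented
discrepancy in the source: the narrative mentions a 47.3% alert response
while the table's totals give 43.17%; the package reproduces the table's
arithmetic and does not attempt to reconcile the narrative figure.
`baseline_comparison()` annualizes the highly-suspicious yield against the
pre-program baseline of 10 possible cases per year:
`baseline_comparison(184, 10, 23)` = `r baseline_comparison(184, 10, 23)`.

## The synthetic cohort: what it does and does not emulate

`generate_cohort()` emulates, per day, Poisson(`daily_volume`) encounter
arrivals (default 440/day, the published average). Each encounter is a
trigger with probability `trigger_prevalence`; the default 0.01 yields an
expected ~4.4 alerts/day, the middle of the published 1–8 alerts/day
operating band. Trigger encounters embed 1–3 patterns sampled uniformly
from the active ruleset (respecting sex scope) and/or an active code;
uniform sampling is arbitrary — no per-pattern hit distribution was ever
published. 40% of trigger encounters carry a positive ground-truth label
(`truth_fraction`), so the alert stream mixes true-positive-like and
noise-like alerts the way a real queue does (most reviewed alerts were not
confirmed cases). Trigger patients return once with probability 0.2,
exercising longitudinal re-alerting.

Benign encounters draw from a fixed sentence pool that is verified against
the ruleset up front (a pool that cannot avoid the vocabulary is an error);
the pool deliberately includes near-miss confounders — "analysis",
"annual", "physical therapist" — that a substring matcher would
false-positive on. Benign diagnoses come from a small pool of common codes
verified against the active code patterns.

The generator makes no attempt at realistic clinical language, demographic
realism beyond the sex mix, or actual trafficking prevalence. Passing
tests therefore demonstrate the *mechanics* — matching, versioning,
queueing, arithmetic — on data whose ground truth is known by
construction; they say nothing about real-world sensitivity or positive
predictive value, which the confidential source data and subjective review
make unreproducible by design.

All randomness flows from one global RNG stream seeded once per run, with
draws in documented order (daily volume, then per encounter: demographics,
trigger flag, content, repeat-visit schedule); inserting a generator stage
reorders the stream and is a breaking change the determinism tests flag.

## Problem sizes and numerical conventions

The test suite runs the full pipeline at desk scale: the reproduction of
the period funnel generates ~30 encounters/day over the 23-month window
with per-period trigger prevalence set from the published alert volumes,
and per-month review capacity and suspicion rates set from the published
fractions, then checks the recomputed percentages within three binomial
standard errors. The calibration check runs the full default cohort (440
encounters/day for 30 days). These sizes are the package's chosen balance
between statistical resolution and quick iteration.

Other conventions: timestamps are ISO-8601, compared and stored in UTC
(batch windows need unambiguous ordering); evidence spans are 0-based,
end-exclusive character offsets that re-extract exactly the matched text;
empty notes and empty diagnosis lists are legal and simply never match;
unknown note types map to `other` with a warning rather than an error,
since real feeds vary.

## Limitations

* The phenotype is purely lexical; misspellings outside the vocabulary
  (only *rapped* is explicitly included), negated mentions ("denies
  abuse") and templated boilerplate all hit or miss verbatim.
* The utilization threshold and navigator capacities are user inputs, not
  published values.
* The social-determinants attributes and the inference logic beyond
  keyword/code matching were never specified in the source and are not
  represented.
* Sensitivity and screened-in rates computed on synthetic cohorts are
  properties of the generator, not estimates for any real population.
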