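#' Synthetic cohort configuration
#'
#' Defines a seeded synthetic hospital encounter stream: arrivals are
#' Poisson at `daily_volume` per day (default 440, a mid-sized multi-site
#' hospital feed), and a small fraction (`trigger_prevalence`) of encounters
#' carry planted phenotype triggers so that the sentry fires on the order of
#' 1–8 alerts/day at defaults. Benign encounters are rejection-checked
#' against the generating ruleset so false positives in tests can only come
#' from the deliberately included near-miss confounder templates
#' ("analysis", "therapist", "annual"...), which exercise whole-token
#' matching.
#'
#' @param start_date,end_date Inclusive ISO dates of the stream (defaults
#'   span 30 days).
#' @param daily_volume Mean encounters/day (Poisson).
#' @param trigger_prevalence Probability an encounter carries planted
#'   triggers. The default 0.01 over 440 encounters/day puts expected alerts
#'   in the middle of the 1–8/day operating band.
#' @param sex_mix Named proportions over male/female/unknown.
#' @param repeat_visit_rate Probability a trigger patient returns once for a
#'   later (benign) visit, exercising longitudinal re-alerting.
#' @param truth_fraction Fraction of trigger encounters labeled
#'   trafficking-positive ground truth (default 0.4, so the alert stream
#'   mixes true-positive-like and noise-like alerts as a real queue does).
#' @param seed Single non-negative integer; one global RNG stream per run.
#' @param trigger_templates Sentence templates with a `{X}` slot for the
#'   planted pattern.
#' @param benign_templates Benign sentence pool; must not match the active
#'   ruleset (verified, error otherwise).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(start_date = "2020-01-01",
                          end_date = "2020-01-30",
                          daily_volume = 440,
                          trigger_prevalence = 0.01,
                          sex_mix = c(male = 0.48, female = 0.49, unknown = 0.03),
                          repeat_visit_rate = 0.2,
                          truth_fraction = 0.4,
                          seed = 1L,
                          trigger_templates = default_trigger_templates(),
                          benign_templates = default_benign_templates()) {
  start_date <- parse_date(as.character(start_date))
  end_date <- parse_date(as.character(end_date))
  if (start_date >= end_date) abort("start_date must be before end_date")
  if (daily_volume <= 0) abort("daily_volume must be positive")
  probs <- c(trigger_prevalence, repeat_visit_rate, truth_fraction)
  if (any(probs < 0 | probs > 1)) abort("probabilities must be in [0, 1]")
  if (!setequal(names(sex_mix), c("male", "female", "unknown")) ||
    any(sex_mix < 0) || abs(sum(sex_mix) - 1) > 1e-8) {
    abort("sex_mix must be proportions over male/female/unknown summing to 1")
  }
  structure(
    list(
      start_date = start_date, end_date = end_date,
      daily_volume = daily_volume, trigger_prevalence = trigger_prevalence,
      sex_mix = sex_mix[c("male", "female", "unknown")],
      repeat_visit_rate = repeat_visit_rate,
      truth_fraction = truth_fraction, seed = seed,
      trigger_templates = trigger_templates,
      benign_templates = benign_templates
    ),
    class = "cohort_config"
  )
}

#' @rdname cohort_config
#' @export
default_trigger_templates <- function() {
  c(
    "pt discloses {X} during visit",
    "patient reports {X} to staff",
    "social work consulted regarding {X}",
    "concern for {X} raised by nursing",
    "{X} noted in patient history",
    "screening positive for {X}"
  )
}

#' @rdname cohort_config
#' @export
default_benign_templates <- function() {
  # includes near-miss confounders: "analysis" vs anal, "physical
  # therapist" vs physical abuse, "annual" vs anal, "transported" vs the
  # trans* vocabulary
  c(
    "patient presents with mild headache and was given ibuprofen",
    "routine follow up visit for hypertension management",
    "analysis of labs unremarkable",
    "patient seen by physical therapist for knee pain",
    "nutrition assessment completed no concerns",
    "discharged home in stable condition",
    "annual wellness exam no acute findings",
    "patient transported to radiology for imaging",
    "cough and congestion for three days supportive care advised",
    "medication reconciliation performed at discharge",
    "patient reports improved mobility after surgery",
    "wound healing well no signs of infection"
  )
}

benign_dx_pool <- function() {
  tibble(
    code = c("E11.9", "I10", "J06.9", "M54.5", "K21.9", "R51", "J45.909", "R07.9", "Z00.00"),
    description = c(
      "type 2 diabetes mellitus without complications",
      "essential primary hypertension",
      "acute upper respiratory infection unspecified",
      "low back pain",
      "gastro esophageal reflux disease without esophagitis",
      "headache",
      "unspecified asthma uncomplicated",
      "chest pain unspecified",
      "encounter for general adult medical examination without abnormal findings"
    )
  )
}

# Realize one pattern token sequence as concrete text: each '%' wildcard is
# replaced by a sampled completion (any completion matches, since '%'
# accepts any run including the empty one).
realize_pattern <- function(raw) {
  m <- compile_keyword(raw)
  fills <- c("", "s", "ed", "ing", "al", "ual", "iatric", "ular", "ology")
  words <- vapply(m$tokens, function(tok) {
    while (grepl("%", tok, fixed = TRUE)) {
      tok <- sub("%", sample(fills, 1), tok, fixed = TRUE)
    }
    tok
  }, character(1), USE.NAMES = FALSE)
  paste(words, collapse = " ")
}

#' Plant a phenotype pattern into a note template
#'
#' Substitutes a concrete realization of `pattern` for the template's `{X}`
#' slot; wildcard patterns get a sampled completion (e.g. `"traffic%"` may
#' realize as "trafficking"). The result is guaranteed (and self-checked) to
#' match the compiled pattern.
#'
#' @param template Template string containing `{X}`.
#' @param pattern Keyword pattern string (e.g. `"forced labor"`,
#'   `"psych%"`).
#' @return Note text matched by `compile_keyword(pattern)`.
#' @examples
#' set.seed(1)
#' plant_phrase("pt reports {X}", "forced labor")
#' @export
plant_phrase <- function(template, pattern) {
  if (!grepl("{X}", template, fixed = TRUE)) {
    abort("template must contain the placeholder {X}")
  }
  out <- sub("{X}", realize_pattern(pattern), template, fixed = TRUE)
  if (!keyword_matches(compile_keyword(pattern), out)) {
    abort(sprintf(
      "internal error: planted text '%s' does not match pattern '%s'",
      out, pattern
    )) # nocov
  }
  out
}

#' Generate a seeded synthetic encounter stream with ground truth
#'
#' Emulates a hospital feed against a given active ruleset. Per day the
#' encounter count is Poisson(`daily_volume`); each encounter is a trigger
#' with probability `trigger_prevalence`. Trigger encounters embed 1–3
#' sampled active keyword patterns (respecting the patient's sex scope)
#' into note text and/or attach a sampled active ICD-10 code; a
#' `truth_fraction` subset of them is labeled trafficking-positive ground
#' truth. Benign encounters draw notes from the benign template pool and
#' diagnoses from a benign code pool, both verified against the ruleset up
#' front (an unavoidable collision is an error, not a silent false
#' positive). Trigger patients return for one later benign visit with
#' probability `repeat_visit_rate`, exercising longitudinal re-alerting.
#' A fixed seed gives byte-identical output; all draws come from one global
#' RNG stream in documented order (day volume, then per encounter:
#' demographics, trigger draw, content, repeat-visit draw).
#'
#' @param config A [cohort_config()].
#' @param ruleset A non-empty `sentry_ruleset` the triggers are sampled
#'   from.
#' @return `list(encounters = <ehr_encounters>, truth = <character vector
#'   of trafficking-positive encounter ids>)`.
#' @export
generate_cohort <- function(config, ruleset) {
  stopifnot(inherits(config, "cohort_config"), inherits(ruleset, "sentry_ruleset"))
  if (!nrow(ruleset$keywords) && !nrow(ruleset$codes)) {
    abort("ruleset is empty; nothing to plant")
  }

  # Benign pools must be clean against the ruleset for every sex scope.
  all_kw <- ruleset$keywords
  bad_tpl <- config$benign_templates[vapply(
    config$benign_templates,
    function(tpl) length(match_keyword_rows(all_kw, tokenize_text(tpl))) > 0L,
    logical(1)
  )]
  if (length(bad_tpl)) {
    abort(sprintf(
      "benign template(s) match the active ruleset: %s",
      paste(bad_tpl, collapse = " | ")
    ))
  }
  bdx <- benign_dx_pool()
  if (nrow(ruleset$codes)) {
    bn <- normalize_code(bdx$code)
    clash <- vapply(bn, function(x) {
      any(
        (ruleset$codes$match_mode == "prefix" & startsWith(x, ruleset$codes$normalized)) |
          (ruleset$codes$match_mode == "exact" & x == ruleset$codes$normalized)
      )
    }, logical(1))
    desc_clash <- if (ruleset$match_descriptions) {
      vapply(bdx$description, function(d) {
        any(vapply(ruleset$codes$desc_matcher, function(m) {
          !is.null(m) && keyword_matches(m, d)
        }, logical(1)))
      }, logical(1))
    } else {
      rep(FALSE, nrow(bdx))
    }
    if (any(clash | desc_clash)) {
      abort(sprintf(
        "benign diagnosis pool collides with active codes: %s",
        paste(bdx$code[clash | desc_clash], collapse = ", ")
      ))
    }
  }

  days <- seq(config$start_date, config$end_date, by = "day")
  note_types <- c("social_work", "care_coordination", "ed_triage", "other")

  with_seed(config$seed, {
    n_day <- stats::rpois(length(days), config$daily_volume)
    n_total <- sum(n_day)

    # column accumulators; repeat visits are appended as they are scheduled
    col <- list(
      encounter_id = character(), patient_id = character(),
      start_time = numeric(), encounter_type = character(),
      sex = character(), age_years = numeric(),
      notes = list(), diagnoses = list(), is_trigger = logical(),
      is_truth = logical()
    )
    k <- 0L
    add_row <- function(eid, pid, st, typ, sex, age, notes, dx, trig, truth) {
      k <<- k + 1L
      col$encounter_id[k] <<- eid
      col$patient_id[k] <<- pid
      col$start_time[k] <<- st
      col$encounter_type[k] <<- typ
      col$sex[k] <<- sex
      col$age_years[k] <<- age
      col$notes[[k]] <<- notes
      col$diagnoses[[k]] <<- dx
      col$is_trigger[k] <<- trig
      col$is_truth[k] <<- truth
    }
    mk_notes <- function(eid, texts, st) {
      n <- length(texts)
      tibble::new_tibble(list(
        note_id = sprintf("%s-N%d", eid, seq_len(n)),
        note_type = sample(note_types, n, replace = TRUE),
        created_at = as.POSIXct(st + 1800 * seq_len(n),
          origin = "1970-01-01", tz = "UTC"
        ),
        text = texts
      ), nrow = n)
    }
    mk_dx <- function(codes, descs, st) {
      if (!length(codes)) {
        return(empty_diagnoses())
      }
      tibble::new_tibble(list(
        code = codes, description = descs,
        coded_at = as.POSIXct(rep(st + 3600, length(codes)),
          origin = "1970-01-01", tz = "UTC"
        )
      ), nrow = length(codes))
    }
    benign_content <- function(eid, st) {
      texts <- sample(config$benign_templates, sample(1:2, 1))
      ndx <- sample(0:2, 1)
      pick <- if (ndx) sample.int(nrow(bdx), ndx) else integer()
      list(
        notes = mk_notes(eid, texts, st),
        dx = mk_dx(bdx$code[pick], bdx$description[pick], st)
      )
    }

    i_enc <- 0L
    i_pat <- 0L
    for (d in seq_along(days)) {
      day0 <- as.numeric(as.POSIXct(paste0(format(days[d]), " 00:00:00"), tz = "UTC"))
      for (j in seq_len(n_day[d])) {
        i_enc <- i_enc + 1L
        i_pat <- i_pat + 1L
        eid <- sprintf("E%07d", i_enc)
        pid <- sprintf("P%07d", i_pat)
        sex <- sample(names(config$sex_mix), 1, prob = config$sex_mix)
        age <- round(stats::runif(1, 18, 85))
        typ <- sample(c("ED", "outpatient", "inpatient"), 1, prob = c(0.5, 0.35, 0.15))
        st <- day0 + round(stats::runif(1, 6 * 3600, 22 * 3600))
        trig <- stats::runif(1) < config$trigger_prevalence

        if (trig) {
          elig <- eligible_keywords(ruleset$keywords, sex)
          mode <- if (nrow(ruleset$codes) && nrow(elig)) {
            sample(c("keyword", "code", "both"), 1, prob = c(0.6, 0.2, 0.2))
          } else if (nrow(elig)) "keyword" else "code"
          texts <- sample(config$benign_templates, 1)
          dx_codes <- character()
          dx_descs <- character()
          if (mode %in% c("keyword", "both")) {
            npat <- sample.int(min(3L, nrow(elig)), 1)
            pats <- elig$raw[sample.int(nrow(elig), npat)]
            texts <- c(
              vapply(pats, function(p) {
                plant_phrase(sample(config$trigger_templates, 1), p)
              }, character(1), USE.NAMES = FALSE),
              texts
            )
          }
          if (mode %in% c("code", "both")) {
            ci <- sample.int(nrow(ruleset$codes), 1)
            dx_codes <- gsub("[[:space:]]", "", ruleset$codes$raw_code[ci])
            dx_descs <- ruleset$codes$description[ci]
          }
          truth <- stats::runif(1) < config$truth_fraction
          add_row(
            eid, pid, st, typ, sex, age,
            mk_notes(eid, texts, st), mk_dx(dx_codes, dx_descs, st),
            TRUE, truth
          )
          # one possible benign return visit (longitudinal re-alert bait)
          if (stats::runif(1) < config$repeat_visit_rate) {
            delta <- sample.int(60, 1)
            rd <- days[d] + delta
            if (rd <= config$end_date) {
              i_enc <- i_enc + 1L
              reid <- sprintf("E%07d", i_enc)
              rst <- day0 + delta * 86400 + round(stats::runif(1, 6 * 3600, 22 * 3600))
              bc <- benign_content(reid, rst)
              add_row(
                reid, pid, rst, sample(c("ED", "outpatient"), 1), sex, age,
                bc$notes, bc$dx, FALSE, FALSE
              )
            }
          }
        } else {
          bc <- benign_content(eid, st)
          add_row(eid, pid, st, typ, sex, age, bc$notes, bc$dx, FALSE, FALSE)
        }
      }
    }

    enc <- tibble(
      encounter_id = col$encounter_id,
      patient_id = col$patient_id,
      start_time = as.POSIXct(col$start_time, origin = "1970-01-01", tz = "UTC"),
      facility_id = "SYN-H1",
      encounter_type = col$encounter_type,
      sex = col$sex,
      age_years = col$age_years,
      disposition = ifelse(col$encounter_type == "inpatient", "admitted", "home"),
      notes = col$notes,
      diagnoses = col$diagnoses
    )
    ord <- order(enc$start_time, enc$encounter_id)
    enc <- validate_encounters(enc[ord, ])
    list(
      encounters = enc,
      truth = col$encounter_id[col$is_truth],
      trigger_ids = col$encounter_id[col$is_trigger]
    )
  })
}

#' Scan an encounter stream in daily batches
#'
#' Convenience wrapper over [run_batch()]: groups encounters by UTC calendar
#' day, scans each day as one batch (window = 24 h) threading the alert
#' history through, and returns all alerts plus the per-day alert counts.
#'
#' @param encounters An `ehr_encounters` tibble.
#' @param versions A `ruleset_history`.
#' @param config A [sentry_config()].
#' @param history An `alert_history` to start from.
#' @return `list(alerts, history, daily = tibble(day, n_alerts))`.
#' @export
scan_daily <- function(encounters, versions, config = sentry_config(),
                       history = new_alert_history()) {
  day <- as.Date(encounters$start_time, tz = "UTC")
  all_days <- sort(unique(day))
  alerts <- list()
  n_alerts <- integer(length(all_days))
  for (d in seq_along(all_days)) {
    batch <- encounters[day == all_days[d], ]
    res <- run_batch(
      batch, versions,
      batch_time = as.POSIXct(paste0(format(all_days[d]), " 23:59:59"), tz = "UTC"),
      history = history, config = config, batch_minutes = 1440
    )
    history <- res$history
    n_alerts[d] <- nrow(res$alerts)
    if (nrow(res$alerts)) alerts[[length(alerts) + 1L]] <- res$alerts
  }
  list(
    alerts = if (length(alerts)) bind_rows(alerts) else empty_alerts(),
    history = history,
    daily = tibble(day = all_days, n_alerts = n_alerts)
  )
}
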