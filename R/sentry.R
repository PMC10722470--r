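#' Sentry configuration
#'
#' Knobs for the scanning engine. The emergency-department utilization rule
#' fires when a patient accumulates at least `utilization_threshold` ED
#' encounters (including the current one) within `utilization_window_days`;
#' the published phenotype names increased health-care utilization as a
#' mined signal without quantifying it, so the default (>= 4 ED visits in 90
#' days) is an artifact decision, exposed here as a knob.
#' `longitudinal_realert` re-surfaces every subsequent visit of a previously
#' alerted patient, supporting consistent navigator contact over time.
#'
#' @param utilization_window_days Lookback window in days.
#' @param utilization_threshold ED visit count that trips the flag.
#' @param utilization_enabled Logical; disable the utilization rule.
#' @param longitudinal_realert Logical; disable repeat-visit re-alerting.
#' @return A list of class `sentry_config`.
#' @export
sentry_config <- function(utilization_window_days = 90,
                          utilization_threshold = 4,
                          utilization_enabled = TRUE,
                          longitudinal_realert = TRUE) {
  stopifnot(utilization_window_days > 0, utilization_threshold >= 1)
  structure(
    list(
      utilization_window_days = utilization_window_days,
      utilization_threshold = utilization_threshold,
      utilization_enabled = isTRUE(utilization_enabled),
      longitudinal_realert = isTRUE(longitudinal_realert)
    ),
    class = "sentry_config"
  )
}

#' Create an empty alert history
#'
#' The history is the sentry's cross-batch memory: which patients have ever
#' alerted (drives repeat re-alerting), which encounters have already
#' alerted (makes batch re-runs idempotent), and the patient ED-visit log
#' that feeds the utilization rule.
#'
#' @return A list of class `alert_history`.
#' @export
new_alert_history <- function() {
  structure(
    list(
      alerted_patients = character(),
      alerted_encounters = character(),
      ed_encounter_id = character(),
      ed_patient_id = character(),
      ed_start = numeric() # POSIX seconds, UTC
    ),
    class = "alert_history"
  )
}

#' @export
print.alert_history <- function(x, ...) {
  cat(sprintf(
    "<alert_history> %d alerted patient(s), %d alerted encounter(s), %d ED visit(s) logged\n",
    length(x$alerted_patients), length(x$alerted_encounters),
    length(x$ed_encounter_id)
  ))
  invisible(x)
}

empty_evidence <- function() {
  tibble(
    pattern_raw = character(), source = character(), source_id = character(),
    span_start = integer(), span_end = integer(), matched_text = character()
  )
}

empty_alerts <- function() {
  tibble(
    alert_id = character(), encounter_id = character(),
    patient_id = character(), fired_at = as.POSIXct(character(), tz = "UTC"),
    is_repeat = logical(), status = character(), evidence = list()
  )
}

# Keyword patterns applicable to a patient of the given sex; unknown sex
# receives the union of all scopes (conservative sensitivity).
eligible_keywords <- function(kw, sex) {
  if (sex == "unknown") {
    return(kw)
  }
  keep <- kw$sex_scope == "any" |
    (kw$sex_scope == "male_only" & sex == "male") |
    (kw$sex_scope == "female_only" & sex == "female")
  kw[keep, ]
}

# Indices of keyword rows matching the tokenized text. Single-token
# literals go through one hashed set lookup; wildcards and multi-word
# patterns use the compiled matcher. Agrees with keyword_matches() by
# construction (property-tested against it).
match_keyword_rows <- function(kw, tk) {
  n <- nrow(kw)
  if (!n || !length(tk$tokens)) {
    return(integer())
  }
  tokset <- unique(tk$tokens)
  hits <- logical(n)
  lit1 <- kw$n_tokens == 1L & !kw$has_wild
  hits[lit1] <- kw$normalized[lit1] %in% tokset
  for (i in which(!lit1)) {
    m <- kw$matcher[[i]]
    if (kw$n_tokens[i] == 1L) {
      hits[i] <- any(grepl(m$regexes[1], tokset))
    } else {
      lits <- m$tokens[!grepl("%", m$tokens, fixed = TRUE)]
      if (all(lits %in% tokset)) {
        hits[i] <- length(matcher_starts(m, tk$tokens)) > 0L
      }
    }
  }
  which(hits)
}

span_from_tk <- function(matcher, tk, text) {
  st <- matcher_starts(matcher, tk$tokens)
  i <- st[1]
  j <- i + length(matcher$tokens) - 1L
  list(
    span_start = tk$start[i] - 1L, # 0-based inclusive
    span_end = tk$end[j], # 0-based exclusive
    matched_text = substring(text, tk$start[i], tk$end[j])
  )
}

# Evidence accumulator: plain parallel vectors, materialized into a tibble
# only when an alert actually fires.
ev_new <- function() {
  list(
    pattern_raw = character(), source = character(), source_id = character(),
    span_start = integer(), span_end = integer(), matched_text = character()
  )
}

ev_add <- function(ev, pattern_raw, source, source_id,
                   span_start = NA_integer_, span_end = NA_integer_,
                   matched_text = NA_character_) {
  ev$pattern_raw <- c(ev$pattern_raw, pattern_raw)
  ev$source <- c(ev$source, source)
  ev$source_id <- c(ev$source_id, source_id)
  ev$span_start <- c(ev$span_start, as.integer(span_start))
  ev$span_end <- c(ev$span_end, as.integer(span_end))
  ev$matched_text <- c(ev$matched_text, matched_text)
  ev
}

ev_tibble <- function(ev) {
  out <- tibble::new_tibble(ev, nrow = length(ev$pattern_raw))
  distinct(out, .data$pattern_raw, .data$source, .data$source_id,
    .keep_all = TRUE
  )
}

# Core scanner over scalar fields plus the nested note/diagnosis tables;
# returns NULL or a list(row) ready to become one alert tibble row.
scan_core <- function(encounter_id, patient_id, sex, encounter_type,
                      start_time, notes, dx, rules, history, config,
                      fired_at) {
  ev <- ev_new()

  kw <- eligible_keywords(rules$keywords, sex)
  if (nrow(notes) && nrow(kw)) {
    for (j in seq_len(nrow(notes))) {
      tk <- tokenize_text(notes$text[j])
      for (i in match_keyword_rows(kw, tk)) {
        sp <- span_from_tk(kw$matcher[[i]], tk, notes$text[j])
        ev <- ev_add(
          ev, kw$raw[i], "note_text", notes$note_id[j],
          sp$span_start, sp$span_end, sp$matched_text
        )
      }
    }
  }

  cd <- rules$codes
  if (nrow(dx) && nrow(cd)) {
    dxn <- normalize_code(dx$code)
    for (j in seq_len(nrow(dx))) {
      hit <- (cd$match_mode == "exact" & cd$normalized == dxn[j]) |
        (cd$match_mode == "prefix" & startsWith(dxn[j], cd$normalized))
      for (i in which(hit)) {
        ev <- ev_add(
          ev, cd$raw_code[i], "diagnosis_code", dx$code[j],
          matched_text = dx$code[j]
        )
      }
      if (rules$match_descriptions && nzchar(dx$description[j])) {
        tk <- tokenize_text(dx$description[j])
        if (length(tk$tokens)) {
          for (i in seq_len(nrow(cd))) {
            m <- cd$desc_matcher[[i]]
            if (is.null(m)) next
            if (length(matcher_starts(m, tk$tokens))) {
              sp <- span_from_tk(m, tk, dx$description[j])
              ev <- ev_add(
                ev, cd$raw_code[i], "diagnosis_description", dx$code[j],
                sp$span_start, sp$span_end, sp$matched_text
              )
            }
          }
        }
      }
    }
  }

  if (config$utilization_enabled && encounter_type == "ED") {
    win <- config$utilization_window_days * 86400
    t0 <- as.numeric(start_time)
    n_ed <- 1L + sum(
      history$ed_patient_id == patient_id &
        history$ed_encounter_id != encounter_id &
        history$ed_start > t0 - win &
        history$ed_start <= t0
    )
    if (n_ed >= config$utilization_threshold) {
      ev <- ev_add(
        ev, "ed_utilization", "utilization", patient_id,
        matched_text = sprintf(
          "%d ED visits in %d days", n_ed, config$utilization_window_days
        )
      )
    }
  }

  is_repeat <- patient_id %in% history$alerted_patients
  if (is_repeat && config$longitudinal_realert) {
    ev <- ev_add(
      ev, "longitudinal_followup", "utilization", patient_id,
      matched_text = "subsequent visit of previously alerted patient"
    )
  }

  if (!length(ev$pattern_raw)) {
    return(NULL)
  }
  list(
    alert_id = paste0("A-", fnv1a32(paste(encounter_id, format_utc(fired_at)))),
    encounter_id = encounter_id,
    patient_id = patient_id,
    fired_at = fired_at,
    is_repeat = is_repeat,
    status = "pending",
    evidence = list(ev_tibble(ev))
  )
}

alerts_from_rows <- function(rows) {
  if (!length(rows)) {
    return(empty_alerts())
  }
  tibble(
    alert_id = map_chr(rows, "alert_id"),
    encounter_id = map_chr(rows, "encounter_id"),
    patient_id = map_chr(rows, "patient_id"),
    fired_at = as.POSIXct(
      vapply(rows, function(r) as.numeric(r$fired_at), numeric(1)),
      origin = "1970-01-01", tz = "UTC"
    ),
    is_repeat = map_lgl(rows, "is_repeat"),
    status = map_chr(rows, "status"),
    evidence = lapply(rows, function(r) r$evidence[[1]])
  )
}

#' Scan one encounter against a ruleset
#'
#' Applies the active computational phenotype to a single encounter: every
#' eligible keyword pattern (sex scope respected) is matched against each
#' note's text, diagnosis codes are compared in normalized form (prefix-mode
#' patterns match code extensions, e.g. pattern T74.21 matches recorded
#' T74.21XA), code descriptions are matched as key phrases against the
#' diagnosis description text when the ruleset enables it, and the ED
#' utilization rule is evaluated against the history's visit log. An alert
#' is returned iff at least one signal fires; its evidence lists every
#' distinct (pattern, source) hit with exact character spans for text
#' matches (0-based, end-exclusive). Previously alerted patients re-alert
#' on any subsequent visit (evidence tagged `longitudinal_followup`) when
#' the config enables it, and carry `is_repeat = TRUE`.
#'
#' @param enc One-row `ehr_encounters` tibble.
#' @param rules A `sentry_ruleset` from [assemble_ruleset_as_of()].
#' @param history An `alert_history`; read-only here (see [run_batch()] for
#'   the stateful loop).
#' @param config A [sentry_config()].
#' @param fired_at Alert timestamp; defaults to the encounter start time
#'   ([run_batch()] passes the batch time).
#' @return A one-row alert tibble, or `NULL` if nothing fired.
#' @export
scan_encounter <- function(enc, rules, history = new_alert_history(),
                           config = sentry_config(), fired_at = NULL) {
  stopifnot(nrow(enc) == 1L)
  fired_at <- fired_at %||% enc$start_time[1]
  if (is.character(fired_at)) fired_at <- parse_utc(fired_at)
  row <- scan_core(
    enc$encounter_id[1], enc$patient_id[1], enc$sex[1],
    enc$encounter_type[1], enc$start_time[1],
    enc$notes[[1]], enc$diagnoses[[1]], rules, history, config, fired_at
  )
  if (is.null(row)) {
    return(NULL)
  }
  alerts_from_rows(list(row))
}

# Shared driver: scan encounters in a fixed order against fixed rules,
# threading the history. Used by run_batch (id order) and
# retrospective_scan (time order).
scan_loop <- function(encounters, ord, rules, history, config, fired_at) {
  eid <- encounters$encounter_id
  pid <- encounters$patient_id
  sex <- encounters$sex
  typ <- encounters$encounter_type
  st <- encounters$start_time
  notes_l <- encounters$notes
  dx_l <- encounters$diagnoses
  rows <- list()
  for (i in ord) {
    if (eid[i] %in% history$alerted_encounters) next
    fa <- if (is.null(fired_at)) st[i] else fired_at
    row <- scan_core(
      eid[i], pid[i], sex[i], typ[i], st[i],
      notes_l[[i]], dx_l[[i]], rules, history, config, fa
    )
    if (!is.null(row)) {
      rows[[length(rows) + 1L]] <- row
      history$alerted_encounters <- c(history$alerted_encounters, eid[i])
      if (!pid[i] %in% history$alerted_patients) {
        history$alerted_patients <- c(history$alerted_patients, pid[i])
      }
    }
    if (typ[i] == "ED" && !eid[i] %in% history$ed_encounter_id) {
      history$ed_encounter_id <- c(history$ed_encounter_id, eid[i])
      history$ed_patient_id <- c(history$ed_patient_id, pid[i])
      history$ed_start <- c(history$ed_start, as.numeric(st[i]))
    }
  }
  list(alerts = alerts_from_rows(rows), history = history)
}

#' Scan a micro-batch of encounters
#'
#' The live sentry receives encounter data in 15-minute micro-batches (4
#' deliveries per hour). `run_batch()` assembles the ruleset once for the
#' batch date, scans each encounter, and returns the alerts in deterministic
#' `encounter_id` order together with the updated history. Encounters whose
#' start time falls outside the batch window raise a warning but are still
#' scanned with the current batch's ruleset (late-arriving data). Encounters
#' already alerted in the history are skipped, so re-running a batch never
#' duplicates alerts.
#'
#' @param encounters An `ehr_encounters` tibble.
#' @param versions A `ruleset_history`.
#' @param batch_time Batch end time (POSIXct or ISO-8601 string); all alerts
#'   of the batch fire at this time.
#' @param history An `alert_history`, threaded through successive calls.
#' @param config A [sentry_config()].
#' @param batch_minutes Window length in minutes (default 15).
#' @return `list(alerts = <alert tibble>, history = <updated history>)`.
#' @export
run_batch <- function(encounters, versions, batch_time,
                      history = new_alert_history(),
                      config = sentry_config(), batch_minutes = 15) {
  if (is.character(batch_time)) batch_time <- parse_utc(batch_time)
  rules <- assemble_ruleset_as_of(versions, as.Date(batch_time, tz = "UTC"))

  if (nrow(encounters)) {
    outside <- encounters$start_time <= batch_time - batch_minutes * 60 |
      encounters$start_time > batch_time
    if (any(outside)) {
      warn(sprintf(
        "%d encounter(s) outside the %d-minute batch window ending %s; scanned anyway",
        sum(outside), batch_minutes, format_utc(batch_time)
      ))
    }
  }
  scan_loop(
    encounters, order(encounters$encounter_id), rules, history, config,
    fired_at = batch_time
  )
}

#' Retrospective phenotype validation scan
#'
#' Runs a ruleset, assembled as of a fixed date, over an encounter archive
#' in chronological order, as used to validate keyword phrases against
#' previously identified cases. Repeat re-alerting is off by default (the
#' question is what the phenotype itself catches); the utilization rule
#' still sees the archive's own ED history. Alerts fire at their
#' encounter's start time.
#'
#' @param versions A `ruleset_history`.
#' @param as_of Date the ruleset is assembled for.
#' @param store An `ehr_encounters` tibble, or a path to a JSONL encounter
#'   file.
#' @param labels Optional character vector of known-case encounter ids;
#'   unknown ids are an error.
#' @param config A [sentry_config()]; defaults to re-alerting disabled.
#' @return A list of class `retro_report`: `as_of`, `n_encounters`,
#'   `n_alerts`, `alerted` (encounter ids), `per_pattern` (tibble of
#'   per-pattern encounter hit counts), `alerts` (the full alert tibble),
#'   and `sensitivity` (`|alerted ∩ labels| / |labels|`, `NULL` when no
#'   labels are given — never reported as 0 by default).
#' @export
retrospective_scan <- function(versions, as_of, store, labels = NULL,
                               config = sentry_config(longitudinal_realert = FALSE)) {
  if (is.character(store) && length(store) == 1L) {
    store <- read_encounters(store, "jsonl")
  }
  if (!is.null(labels) && length(labels)) {
    unknown <- setdiff(labels, store$encounter_id)
    if (length(unknown)) {
      abort(sprintf(
        "label(s) reference unknown encounter ids: %s",
        paste(unknown, collapse = ", ")
      ))
    }
  }
  as_of <- parse_date(as.character(as_of))
  rules <- assemble_ruleset_as_of(versions, as_of)
  res <- scan_loop(
    store, order(store$start_time, store$encounter_id), rules,
    new_alert_history(), config,
    fired_at = NULL
  )
  alerts <- res$alerts
  per_pattern <- if (nrow(alerts)) {
    ev <- bind_rows(map2(alerts$evidence, alerts$encounter_id, function(e, id) {
      mutate(e, encounter_id = id)
    }))
    ev |>
      distinct(.data$pattern_raw, .data$encounter_id) |>
      dplyr::count(.data$pattern_raw, name = "n_encounters") |>
      arrange(dplyr::desc(.data$n_encounters), .data$pattern_raw)
  } else {
    tibble(pattern_raw = character(), n_encounters = integer())
  }
  sensitivity <- if (!is.null(labels) && length(labels)) {
    length(intersect(alerts$encounter_id, labels)) / length(labels)
  } else {
    NULL
  }
  structure(
    list(
      as_of = as_of, n_encounters = nrow(store), n_alerts = nrow(alerts),
      alerted = alerts$encounter_id, per_pattern = per_pattern,
      sensitivity = sensitivity, alerts = alerts
    ),
    class = "retro_report"
  )
}

#' @export
print.retro_report <- function(x, ...) {
  cat(sprintf(
    "<retro_report> ruleset as of %s: %d/%d encounters alerted%s\n",
    format(x$as_of), x$n_alerts, x$n_encounters,
    if (!is.null(x$sensitivity)) {
      sprintf("; sensitivity on labels %.3f", x$sensitivity)
    } else {
      ""
    }
  ))
  invisible(x)
}
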