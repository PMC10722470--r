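#' Read and write alert and outcome streams
#'
#' Alerts serialize to JSON-lines, one alert object per line with its
#' nested evidence list; screening outcomes to one flat object per line.
#' Both round-trip exactly (timestamps to the second).
#'
#' @param alerts Alert tibble as produced by [run_batch()].
#' @param outcomes Outcome tibble as produced by [simulate_screening()].
#' @param path File path.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @export
write_alerts <- function(alerts, path) {
  lines <- vapply(seq_len(nrow(alerts)), function(i) {
    ev <- alerts$evidence[[i]]
    jsonlite::toJSON(
      list(
        alert_id = alerts$alert_id[i],
        encounter_id = alerts$encounter_id[i],
        patient_id = alerts$patient_id[i],
        fired_at = format_utc(alerts$fired_at[i]),
        is_repeat = alerts$is_repeat[i],
        status = alerts$status[i],
        evidence = lapply(seq_len(nrow(ev)), function(j) {
          e <- list(
            pattern_raw = ev$pattern_raw[j], source = ev$source[j],
            source_id = ev$source_id[j], matched_text = ev$matched_text[j]
          )
          if (!is.na(ev$span_start[j])) {
            e$span_start <- ev$span_start[j]
            e$span_end <- ev$span_end[j]
          }
          e
        })
      ),
      auto_unbox = TRUE, digits = NA
    )
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_alerts
#' @export
read_alerts <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(empty_alerts())
  }
  rows <- lapply(lines, function(ln) {
    r <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    ev <- if (length(r$evidence)) {
      bind_rows(lapply(r$evidence, function(e) {
        tibble(
          pattern_raw = e$pattern_raw, source = e$source,
          source_id = e$source_id,
          span_start = as.integer(e$span_start %||% NA_integer_),
          span_end = as.integer(e$span_end %||% NA_integer_),
          matched_text = e$matched_text
        )
      }))
    } else {
      empty_evidence()
    }
    tibble(
      alert_id = r$alert_id, encounter_id = r$encounter_id,
      patient_id = r$patient_id, fired_at = parse_utc(r$fired_at),
      is_repeat = isTRUE(r$is_repeat), status = r$status,
      evidence = list(ev)
    )
  })
  bind_rows(rows)
}

#' @rdname write_alerts
#' @export
write_outcomes <- function(outcomes, path) {
  lines <- vapply(seq_len(nrow(outcomes)), function(i) {
    jsonlite::toJSON(
      list(
        alert_id = outcomes$alert_id[i],
        navigator_id = outcomes$navigator_id[i],
        reviewed_at = format_utc(outcomes$reviewed_at[i]),
        disposition = outcomes$disposition[i],
        contact_made = outcomes$contact_made[i]
      ),
      auto_unbox = TRUE, digits = NA
    )
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_alerts
#' @export
read_outcomes <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(empty_outcomes())
  }
  bind_rows(lapply(lines, function(ln) {
    r <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    tibble(
      alert_id = r$alert_id, navigator_id = r$navigator_id,
      reviewed_at = parse_utc(r$reviewed_at),
      disposition = r$disposition, contact_made = isTRUE(r$contact_made)
    )
  }))
}

#' Persist and restore an alert history
#'
#' JSON serialization of the sentry's cross-batch memory, so a live loop
#' can stop and resume.
#'
#' @param history An `alert_history`.
#' @param path File path.
#' @return `read_history()` returns an `alert_history`; `write_history()`
#'   returns `path` invisibly.
#' @export
write_history <- function(history, path) {
  jsonlite::write_json(
    list(
      alerted_patients = history$alerted_patients,
      alerted_encounters = history$alerted_encounters,
      ed_encounter_id = history$ed_encounter_id,
      ed_patient_id = history$ed_patient_id,
      ed_start = format_utc(as.POSIXct(history$ed_start,
        origin = "1970-01-01", tz = "UTC"
      ))
    ),
    path,
    digits = NA
  )
  invisible(path)
}

#' @rdname write_history
#' @export
read_history <- function(path) {
  r <- jsonlite::read_json(path, simplifyVector = TRUE)
  h <- new_alert_history()
  h$alerted_patients <- as.character(r$alerted_patients)
  h$alerted_encounters <- as.character(r$alerted_encounters)
  h$ed_encounter_id <- as.character(r$ed_encounter_id)
  h$ed_patient_id <- as.character(r$ed_patient_id)
  h$ed_start <- as.numeric(parse_utc(as.character(r$ed_start)))
  h
}
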