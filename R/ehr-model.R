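#' Construct an encounter table
#'
#' Encounters are the unit the sentry scans: one clinical visit with its
#' free-text notes, ICD-10-CM diagnoses and demographics. They are held as a
#' tibble with one row per encounter and list-columns for the nested notes
#' and diagnoses, so the stream works with ordinary dplyr verbs.
#'
#' @param encounter_id,patient_id Opaque identifier strings.
#' @param start_time Visit start, POSIXct or ISO-8601 string (stored in UTC).
#' @param facility_id Facility identifier string.
#' @param encounter_type One of `"ED"`, `"inpatient"`, `"outpatient"`.
#' @param sex One of `"male"`, `"female"`, `"unknown"`.
#' @param age_years Non-negative number.
#' @param notes List of note tables as built by [note_document()]; one
#'   element per encounter.
#' @param diagnoses List of diagnosis tables as built by [diagnosis_code()].
#' @param disposition Free-text disposition string.
#' @return A validated tibble of class `ehr_encounters`.
#' @examples
#' enc <- encounter_tbl(
#'   encounter_id = "E1", patient_id = "P1",
#'   start_time = "2020-01-05T10:00:00Z", facility_id = "H1",
#'   encounter_type = "ED", sex = "female", age_years = 34,
#'   notes = list(note_document("N1", "social_work",
#'     "2020-01-05T10:30:00Z", "routine visit")),
#'   diagnoses = list(diagnosis_code("I10", "essential hypertension",
#'     "2020-01-05T11:00:00Z"))
#' )
#' @export
encounter_tbl <- function(encounter_id, patient_id, start_time, facility_id,
                          encounter_type, sex, age_years,
                          notes = NULL, diagnoses = NULL,
                          disposition = "") {
  n <- length(encounter_id)
  if (is.null(notes)) notes <- rep(list(empty_notes()), n)
  if (is.null(diagnoses)) diagnoses <- rep(list(empty_diagnoses()), n)
  if (is.character(start_time)) start_time <- parse_utc(start_time)
  out <- tibble(
    encounter_id = as.character(encounter_id),
    patient_id = as.character(patient_id),
    start_time = lubridate::with_tz(start_time, "UTC"),
    facility_id = as.character(facility_id),
    encounter_type = as.character(encounter_type),
    sex = as.character(sex),
    age_years = as.numeric(age_years),
    disposition = as.character(rep_len(disposition, n)),
    notes = notes,
    diagnoses = diagnoses
  )
  validate_encounters(out)
}

#' @rdname encounter_tbl
#' @param note_id Note identifier, unique within its encounter.
#' @param note_type One of `"social_work"`, `"care_coordination"`,
#'   `"ed_triage"`, `"other"`. Unrecognised strings are mapped to `"other"`
#'   with a warning (real note feeds vary).
#' @param created_at Note creation time (POSIXct or ISO-8601 string).
#' @param text Note body; may be empty.
#' @export
note_document <- function(note_id, note_type, created_at, text = "") {
  known <- c("social_work", "care_coordination", "ed_triage", "other")
  note_type <- as.character(note_type)
  odd <- !note_type %in% known
  if (any(odd)) {
    warn(sprintf(
      "unknown note_type %s mapped to 'other'",
      paste(unique(note_type[odd]), collapse = ", ")
    ))
    note_type[odd] <- "other"
  }
  if (is.character(created_at)) created_at <- parse_utc(created_at)
  tibble(
    note_id = as.character(note_id),
    note_type = note_type,
    created_at = lubridate::with_tz(created_at, "UTC"),
    text = as.character(text)
  )
}

#' @rdname encounter_tbl
#' @param code ICD-10-CM code as recorded (e.g. `"T74.21"`, `"T76.21XA"`).
#' @param description Free-text code description.
#' @param coded_at Coding time (POSIXct or ISO-8601 string).
#' @export
diagnosis_code <- function(code, description = "", coded_at) {
  if (is.character(coded_at)) coded_at <- parse_utc(coded_at)
  tibble(
    code = as.character(code),
    description = as.character(rep_len(description, length(code))),
    coded_at = lubridate::with_tz(coded_at, "UTC")
  )
}

empty_notes <- function() {
  tibble(
    note_id = character(), note_type = character(),
    created_at = as.POSIXct(character(), tz = "UTC"), text = character()
  )
}

empty_diagnoses <- function() {
  tibble(
    code = character(), description = character(),
    coded_at = as.POSIXct(character(), tz = "UTC")
  )
}

empty_encounters <- function() {
  encounter_tbl(
    encounter_id = character(), patient_id = character(),
    start_time = as.POSIXct(character(), tz = "UTC"),
    facility_id = character(), encounter_type = character(),
    sex = character(), age_years = numeric(),
    notes = list(), diagnoses = list(), disposition = character()
  )
}

# Uppercase, strip dot and internal whitespace: "T76.21 XA" -> "T7621XA".
normalize_code <- function(code) {
  gsub("[.[:space:]]", "", toupper(code))
}

#' Validate an encounter table
#'
#' Enforces the stream invariants: non-empty unique `encounter_id`, legal
#' `sex` and `encounter_type` values, non-negative age, note timestamps no
#' earlier than 24 h before the visit start, note ids unique within their
#' encounter, and diagnosis codes that normalize (uppercase, dot and
#' whitespace stripped) to non-empty alphanumeric strings.
#'
#' @param x A tibble shaped like [encounter_tbl()] output.
#' @param where Optional character vector of per-row source labels (e.g.
#'   `"line 3"`) used in error messages.
#' @return `x`, classed `ehr_encounters`, invisibly unchanged otherwise.
#' @export
validate_encounters <- function(x, where = NULL) {
  loc <- function(i) if (is.null(where)) sprintf("record %d", i) else where[i]
  fail <- function(i, field, msg) {
    abort(sprintf("%s, field '%s': %s", loc(i), field, msg),
      class = "sentryr_validation_error"
    )
  }

  bad <- which(is.na(x$encounter_id) | x$encounter_id == "")
  if (length(bad)) fail(bad[1], "encounter_id", "must be non-empty")
  dup <- which(duplicated(x$encounter_id))
  if (length(dup)) {
    fail(dup[1], "encounter_id", sprintf("duplicate id '%s'", x$encounter_id[dup[1]]))
  }
  bad <- which(is.na(x$patient_id) | x$patient_id == "")
  if (length(bad)) fail(bad[1], "patient_id", "must be non-empty")
  bad <- which(!x$sex %in% c("male", "female", "unknown"))
  if (length(bad)) {
    fail(bad[1], "sex", sprintf("'%s' is not male/female/unknown", x$sex[bad[1]]))
  }
  bad <- which(!x$encounter_type %in% c("ED", "inpatient", "outpatient"))
  if (length(bad)) {
    fail(
      bad[1], "encounter_type",
      sprintf("'%s' is not ED/inpatient/outpatient", x$encounter_type[bad[1]])
    )
  }
  bad <- which(is.na(x$age_years) | x$age_years < 0)
  if (length(bad)) fail(bad[1], "age_years", "must be a non-negative number")
  bad <- which(is.na(x$start_time))
  if (length(bad)) fail(bad[1], "start_time", "missing or unparseable")

  for (i in seq_len(nrow(x))) {
    nt <- x$notes[[i]]
    if (nrow(nt)) {
      if (anyDuplicated(nt$note_id)) {
        fail(i, "notes.note_id", "note ids must be unique within an encounter")
      }
      early <- nt$created_at < x$start_time[i] - 24 * 3600
      if (any(early)) {
        fail(
          i, "notes.created_at",
          sprintf(
            "note '%s' created more than 24 h before visit start",
            nt$note_id[which(early)[1]]
          )
        )
      }
    }
    dx <- x$diagnoses[[i]]
    if (nrow(dx)) {
      norm <- normalize_code(dx$code)
      bad <- norm == "" | !grepl("^[A-Z0-9]+$", norm)
      if (any(bad)) {
        fail(
          i, "diagnoses.code",
          sprintf("code '%s' does not normalize to alphanumeric", dx$code[which(bad)[1]])
        )
      }
    }
  }
  class(x) <- unique(c("ehr_encounters", class(x)))
  x
}

encounter_to_list <- function(x, i) {
  nt <- x$notes[[i]]
  dx <- x$diagnoses[[i]]
  list(
    encounter_id = x$encounter_id[i],
    patient_id = x$patient_id[i],
    start_time = format_utc(x$start_time[i]),
    facility_id = x$facility_id[i],
    encounter_type = x$encounter_type[i],
    sex = x$sex[i],
    age_years = x$age_years[i],
    disposition = x$disposition[i],
    notes = lapply(seq_len(nrow(nt)), function(j) {
      list(
        note_id = nt$note_id[j], note_type = nt$note_type[j],
        created_at = format_utc(nt$created_at[j]), text = nt$text[j]
      )
    }),
    diagnoses = lapply(seq_len(nrow(dx)), function(j) {
      list(
        code = dx$code[j], description = dx$description[j],
        coded_at = format_utc(dx$coded_at[j])
      )
    })
  )
}

req_field <- function(rec, field, loc) {
  v <- rec[[field]]
  if (is.null(v) || length(v) != 1L || is.na(v) || identical(v, "")) {
    abort(sprintf("%s, field '%s': missing or empty", loc, field),
      class = "sentryr_parse_error"
    )
  }
  v
}

encounter_from_list <- function(rec, loc) {
  notes <- rec$notes %||% list()
  dxs <- rec$diagnoses %||% list()
  nt <- if (length(notes)) {
    note_document(
      note_id = map_chr(notes, function(n) as.character(req_field(n, "note_id", loc))),
      note_type = map_chr(notes, function(n) as.character(n$note_type %||% "other")),
      created_at = map_chr(notes, function(n) as.character(req_field(n, "created_at", loc))),
      text = map_chr(notes, function(n) as.character(n$text %||% ""))
    )
  } else {
    empty_notes()
  }
  dx <- if (length(dxs)) {
    diagnosis_code(
      code = map_chr(dxs, function(d) as.character(req_field(d, "code", loc))),
      description = map_chr(dxs, function(d) as.character(d$description %||% "")),
      coded_at = map_chr(dxs, function(d) as.character(req_field(d, "coded_at", loc)))
    )
  } else {
    empty_diagnoses()
  }
  tibble(
    encounter_id = as.character(req_field(rec, "encounter_id", loc)),
    patient_id = as.character(req_field(rec, "patient_id", loc)),
    start_time = parse_utc(as.character(req_field(rec, "start_time", loc))),
    facility_id = as.character(rec$facility_id %||% ""),
    encounter_type = as.character(req_field(rec, "encounter_type", loc)),
    sex = as.character(req_field(rec, "sex", loc)),
    age_years = as.numeric(req_field(rec, "age_years", loc)),
    disposition = as.character(rec$disposition %||% ""),
    notes = list(nt),
    diagnoses = list(dx)
  )
}

#' Read and write encounter streams
#'
#' `read_encounters()` loads an encounter stream from JSON-lines (one
#' encounter object per line; the primary, richer format) or RFC 4180 CSV
#' (one row per encounter, notes and diagnoses as JSON-encoded cells).
#' All type invariants are validated; malformed records are reported with
#' their line number and field. `write_encounters()` is its inverse:
#' write-then-read reproduces the stream field for field, timestamps to the
#' second.
#'
#' @param path File path.
#' @param format `"jsonl"` or `"csv"`.
#' @param encounters An `ehr_encounters` tibble.
#' @return `read_encounters()` returns a validated `ehr_encounters` tibble
#'   in file order; `write_encounters()` returns `path` invisibly.
#' @export
read_encounters <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
      return(empty_encounters())
    }
    rows <- lapply(seq_along(lines), function(i) {
      loc <- sprintf("line %d", i)
      rec <- tryCatch(
        jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
        error = function(e) {
          abort(sprintf("%s: invalid JSON (%s)", loc, conditionMessage(e)),
            class = "sentryr_parse_error"
          )
        }
      )
      encounter_from_list(rec, loc)
    })
    out <- bind_rows(rows)
    validate_encounters(out, where = sprintf("line %d", seq_len(nrow(out))))
  } else {
    df <- utils::read.csv(path,
      colClasses = "character", check.names = FALSE,
      fileEncoding = "UTF-8"
    )
    need <- c(
      "encounter_id", "patient_id", "start_time", "facility_id",
      "encounter_type", "sex", "age_years", "disposition",
      "notes_json", "diagnoses_json"
    )
    missing_cols <- setdiff(need, names(df))
    if (length(missing_cols)) {
      abort(sprintf("csv missing column(s): %s", paste(missing_cols, collapse = ", ")))
    }
    if (!nrow(df)) {
      return(empty_encounters())
    }
    rows <- lapply(seq_len(nrow(df)), function(i) {
      loc <- sprintf("line %d", i + 1L) # header is line 1
      rec <- as.list(df[i, , drop = FALSE])
      rec$age_years <- suppressWarnings(as.numeric(rec$age_years))
      rec$notes <- jsonlite::fromJSON(rec$notes_json, simplifyVector = FALSE)
      rec$diagnoses <- jsonlite::fromJSON(rec$diagnoses_json, simplifyVector = FALSE)
      encounter_from_list(rec, loc)
    })
    out <- bind_rows(rows)
    validate_encounters(out, where = sprintf("line %d", seq_len(nrow(out)) + 1L))
  }
}

#' @rdname read_encounters
#' @export
write_encounters <- function(encounters, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  recs <- lapply(seq_len(nrow(encounters)), function(i) encounter_to_list(encounters, i))
  if (format == "jsonl") {
    lines <- vapply(
      recs,
      function(r) jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA),
      character(1)
    )
    writeLines(lines, path, useBytes = TRUE)
  } else {
    df <- data.frame(
      encounter_id = encounters$encounter_id,
      patient_id = encounters$patient_id,
      start_time = format_utc(encounters$start_time),
      facility_id = encounters$facility_id,
      encounter_type = encounters$encounter_type,
      sex = encounters$sex,
      age_years = encounters$age_years,
      disposition = encounters$disposition,
      notes_json = vapply(
        recs,
        function(r) as.character(jsonlite::toJSON(r$notes, auto_unbox = TRUE, digits = NA)),
        character(1)
      ),
      diagnoses_json = vapply(
        recs,
        function(r) as.character(jsonlite::toJSON(r$diagnoses, auto_unbox = TRUE, digits = NA)),
        character(1)
      ),
      stringsAsFactors = FALSE, check.names = FALSE
    )
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}
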