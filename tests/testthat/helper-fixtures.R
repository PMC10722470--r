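# Shared fixtures and independent oracles.

# Quick single-encounter constructor.
mk_enc <- function(id = "E1", pid = "P1", time = "2020-06-15T10:00:00Z",
                   sex = "female", type = "ED", age = 30,
                   note_texts = character(), codes = character(),
                   code_descs = rep("", length(codes)), facility = "H1") {
  notes <- if (length(note_texts)) {
    note_document(
      note_id = sprintf("%s-N%d", id, seq_along(note_texts)),
      note_type = "social_work", created_at = time, text = note_texts
    )
  } else {
    NULL
  }
  dx <- if (length(codes)) {
    diagnosis_code(codes, code_descs, coded_at = time)
  } else {
    NULL
  }
  encounter_tbl(
    encounter_id = id, patient_id = pid, start_time = time,
    facility_id = facility, encounter_type = type, sex = sex,
    age_years = age,
    notes = if (is.null(notes)) NULL else list(notes),
    diagnoses = if (is.null(dx)) NULL else list(dx)
  )
}

default_versions <- local({
  v <- NULL
  function() {
    if (is.null(v)) v <<- load_ruleset_config(default_ruleset_path())
    v
  }
})

# --- independent wildcard-matching oracle -----------------------------------
# Character-level recursive expansion of the '%' wildcard over one token;
# shares no code with the compiled regex path.
bf_tok_match <- function(p, t) {
  if (p == "") {
    return(t == "")
  }
  h <- substr(p, 1, 1)
  rest <- substr(p, 2, nchar(p))
  if (h == "%") {
    for (i in 0:nchar(t)) {
      if (bf_tok_match(rest, substring(t, i + 1))) {
        return(TRUE)
      }
    }
    return(FALSE)
  }
  nchar(t) > 0 && substr(t, 1, 1) == h && bf_tok_match(rest, substring(t, 2))
}

# Whole-pattern oracle: own tokenizer + sliding window of bf_tok_match.
bf_pattern_matches <- function(pattern, text) {
  ptoks <- strsplit(tolower(pattern), "[^a-z0-9%]+")[[1]]
  ptoks <- ptoks[nzchar(ptoks)]
  ttoks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  ttoks <- ttoks[nzchar(ttoks)]
  k <- length(ptoks)
  n <- length(ttoks)
  if (k == 0 || n < k) {
    return(FALSE)
  }
  for (i in seq_len(n - k + 1)) {
    if (all(vapply(seq_len(k), function(j) {
      bf_tok_match(ptoks[j], ttoks[i + j - 1])
    }, logical(1)))) {
      return(TRUE)
    }
  }
  FALSE
}

# Random pattern / token generators over a 2-letter alphabet.
rand_token <- function() {
  n <- sample(0:6, 1)
  paste(sample(c("a", "b"), n, replace = TRUE), collapse = "")
}
rand_pattern <- function() {
  repeat {
    n <- sample(1:5, 1)
    p <- paste(sample(c("a", "b", "%"), n, replace = TRUE, prob = c(.4, .4, .2)),
      collapse = ""
    )
    if (grepl("[ab]", p)) {
      return(p)
    } # compile_keyword rejects bare '%'
  }
}

# Published period-funnel integers, used as fixture inputs.
published_funnel_counts <- function() {
  tibble::tibble(
    label = c("Sep-Dec 2019", "2020", "Jan-Jul 2021"),
    n_alerts = c(276L, 838L, 649L),
    n_screened = c(94L, 325L, 342L),
    n_suspicious = c(30L, 71L, 83L)
  )
}
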