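#' Compile a keyword pattern into a token matcher
#'
#' Keyword phenotype patterns match whole word tokens, not raw substrings:
#' text is lowercased and split on non-alphanumeric boundaries, so `"abuse"`
#' matches the token "abuse" but not "abusive", and `"anal"` does not fire
#' inside "analysis". A `%` is a SQL-LIKE wildcard for any (possibly empty)
#' character run within a single token (`"traffic%"` matches "trafficking"
#' and "trafficked"). Multi-word patterns (including hyphenated ones such as
#' `"trans-sexual"`, which tokenizes to a bigram) match consecutive tokens.
#' Matching is case-insensitive throughout.
#'
#' @param raw Pattern string, e.g. `"traffic%"`, `"adult abuse"`.
#' @return An object of class `keyword_matcher` with elements `raw`,
#'   `normalized`, `tokens` and `regexes`; use [keyword_matches()] /
#'   [keyword_find_span()] to apply it.
#' @examples
#' m <- compile_keyword("traffic%")
#' keyword_matches(m, "concern for labor trafficking raised")
#' @export
compile_keyword <- function(raw) {
  normalized <- normalize_keyword(raw)
  if (!grepl("[[:alnum:]]", normalized)) {
    abort(sprintf(
      "invalid keyword pattern '%s': contains no literal characters (would match everything)",
      raw
    ))
  }
  tokens <- strsplit(normalized, "[^[:alnum:]%]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  regexes <- paste0("^", gsub("%", "[[:alnum:]]*", tokens, fixed = TRUE), "$")
  structure(
    list(raw = raw, normalized = normalized, tokens = tokens, regexes = regexes),
    class = "keyword_matcher"
  )
}

# lowercase, trim, collapse runs of whitespace
normalize_keyword <- function(raw) {
  gsub("[[:space:]]+", " ", trimws(tolower(raw)))
}

#' @export
print.keyword_matcher <- function(x, ...) {
  cat(sprintf(
    "<keyword_matcher> '%s' (%d token%s%s)\n",
    x$normalized, length(x$tokens), if (length(x$tokens) == 1) "" else "s",
    if (any(grepl("%", x$tokens, fixed = TRUE))) ", wildcard" else ""
  ))
  invisible(x)
}

# Lowercased word tokens with 1-based character positions in the original
# text (tolower preserves offsets).
tokenize_text <- function(text) {
  if (is.na(text) || !nzchar(text)) {
    return(list(tokens = character(), start = integer(), end = integer()))
  }
  low <- tolower(text)
  m <- gregexpr("[[:alnum:]]+", low)[[1]]
  if (m[1] == -1L) {
    return(list(tokens = character(), start = integer(), end = integer()))
  }
  len <- attr(m, "match.length")
  list(
    tokens = substring(low, m, m + len - 1L),
    start = as.integer(m),
    end = as.integer(m + len - 1L)
  )
}

# Positions i such that tokens[i .. i+k-1] match the pattern's k token
# regexes consecutively.
matcher_starts <- function(matcher, tokens) {
  k <- length(matcher$regexes)
  n <- length(tokens)
  if (n < k) {
    return(integer())
  }
  hit <- which(grepl(matcher$regexes[1], tokens[seq_len(n - k + 1L)]))
  if (k == 1L || !length(hit)) {
    return(hit)
  }
  keep <- vapply(hit, function(i) {
    all(vapply(
      seq_len(k - 1L),
      function(j) grepl(matcher$regexes[j + 1L], tokens[i + j]),
      logical(1)
    ))
  }, logical(1))
  hit[keep]
}

#' @rdname compile_keyword
#' @param matcher A `keyword_matcher`.
#' @param text Free text to scan.
#' @return `keyword_matches()`: TRUE iff the pattern matches anywhere in the
#'   text. `keyword_find_span()`: a one-row tibble with the first match's
#'   0-based, end-exclusive character span and the matched text, or NULL.
#' @export
keyword_matches <- function(matcher, text) {
  tk <- tokenize_text(text)
  length(matcher_starts(matcher, tk$tokens)) > 0L
}

#' @rdname compile_keyword
#' @export
keyword_find_span <- function(matcher, text) {
  tk <- tokenize_text(text)
  st <- matcher_starts(matcher, tk$tokens)
  if (!length(st)) {
    return(NULL)
  }
  i <- st[1]
  j <- i + length(matcher$tokens) - 1L
  tibble(
    span_start = tk$start[i] - 1L, # 0-based inclusive
    span_end = tk$end[j], # 0-based exclusive == 1-based inclusive
    matched_text = substring(text, tk$start[i], tk$end[j])
  )
}

empty_keywords <- function() {
  tibble(
    raw = character(), normalized = character(), sex_scope = character(),
    effective_from = as.Date(character()), source_tag = character()
  )
}

empty_codes <- function() {
  tibble(
    raw_code = character(), normalized = character(), match_mode = character(),
    description = character(), effective_from = as.Date(character())
  )
}

#' Load a versioned ruleset configuration
#'
#' A ruleset config is YAML with a top-level `versions:` list; each version
#' has `id`, `effective_from` (ISO date), and optional `add_keywords`
#' (list of `{pattern, sex_scope}`), `remove_keywords`, `add_codes`
#' (list of `{code, match_mode, description}`), `remove_codes`. The optional
#' top-level `match_code_descriptions_from` date turns on evaluation of code
#' descriptions as keyword phrases against diagnosis description text from
#' that date onward (the "simplified to key phrase" behavior).
#'
#' The packaged default config (`default_ruleset_path()`) transcribes the
#' published quarterly phenotype history: the 2019 Q3 baseline vocabulary
#' and ICD-10-CM code list, the 2019 Q4 expansion, the 2020 Q1 additions
#' with the male-specific list, the 2020 Q2, 2020 Q4 and 2021 Q2 additions.
#'
#' @param path Path to the YAML config.
#' @return An object of class `ruleset_history`: a list of validated
#'   versions sorted by `effective_from`.
#' @export
load_ruleset_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("ruleset config not found: %s", path))
  cfg <- yaml::read_yaml(path)
  vs <- cfg$versions
  if (is.null(vs) || !length(vs)) abort("no versions defined in ruleset config")

  versions <- lapply(vs, function(v) {
    if (is.null(v$id) || is.null(v$effective_from)) {
      abort("each version needs 'id' and 'effective_from'")
    }
    mk_kw <- function(items) {
      if (!length(items)) {
        return(tibble(raw = character(), sex_scope = character()))
      }
      tibble(
        raw = map_chr(items, function(x) as.character(x$pattern)),
        sex_scope = map_chr(items, function(x) as.character(x$sex_scope %||% "any"))
      )
    }
    mk_cd <- function(items) {
      if (!length(items)) {
        return(tibble(
          raw_code = character(), match_mode = character(),
          description = character()
        ))
      }
      tibble(
        raw_code = map_chr(items, function(x) as.character(x$code)),
        match_mode = map_chr(items, function(x) as.character(x$match_mode %||% "prefix")),
        description = map_chr(items, function(x) as.character(x$description %||% ""))
      )
    }
    add_kw <- mk_kw(v$add_keywords)
    bad_scope <- setdiff(add_kw$sex_scope, c("any", "male_only", "female_only"))
    if (length(bad_scope)) {
      abort(sprintf(
        "version %s: invalid sex_scope %s", v$id,
        paste(bad_scope, collapse = ", ")
      ))
    }
    bad_mode <- setdiff(mk_cd(v$add_codes)$match_mode, c("exact", "prefix"))
    if (length(bad_mode)) {
      abort(sprintf(
        "version %s: invalid match_mode %s", v$id,
        paste(bad_mode, collapse = ", ")
      ))
    }
    # compile every pattern now so config errors surface at load time
    lapply(add_kw$raw, compile_keyword)
    list(
      version_id = as.character(v$id),
      effective_from = parse_date(as.character(v$effective_from)),
      add_keywords = add_kw,
      remove_keywords = mk_kw(v$remove_keywords),
      add_codes = mk_cd(v$add_codes),
      remove_codes = mk_cd(v$remove_codes)["raw_code"]
    )
  })

  ids <- map_chr(versions, "version_id")
  if (anyDuplicated(ids)) {
    abort(sprintf(
      "duplicate version_id: %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  eff <- as.Date(map_chr(versions, function(v) as.character(v$effective_from)))
  versions <- versions[order(eff)]
  eff <- sort(eff)
  if (any(diff(eff) <= 0)) {
    abort("version effective_from dates must be strictly increasing")
  }

  out <- structure(
    versions,
    class = "ruleset_history",
    match_code_descriptions_from =
      if (!is.null(cfg$match_code_descriptions_from)) {
        parse_date(as.character(cfg$match_code_descriptions_from))
      } else {
        as.Date(NA)
      }
  )
  # replaying the history validates that removals reference active patterns
  assemble_ruleset_as_of(out, max(eff))
  out
}

#' @export
print.ruleset_history <- function(x, ...) {
  cat(sprintf("<ruleset_history> %d version(s)\n", length(x)))
  for (v in x) {
    cat(sprintf(
      "  %s (from %s): +%d/-%d keywords, +%d/-%d codes\n",
      v$version_id, format(v$effective_from),
      nrow(v$add_keywords), nrow(v$remove_keywords),
      nrow(v$add_codes), nrow(v$remove_codes)
    ))
  }
  invisible(x)
}

#' Assemble the active ruleset as of a date
#'
#' Replays the version history in date order: the active set is the union of
#' all additions with `effective_from <= date` minus all removals with
#' `effective_from <= date` (the boundary is inclusive: a version's
#' additions are active on its own effective date). Duplicate keyword
#' entries — same normalized pattern and sex scope — and duplicate
#' normalized codes collapse to one, keeping the earliest effective date;
#' the number collapsed is recorded in the `collapsed_duplicates` attribute.
#'
#' @param versions A `ruleset_history` from [load_ruleset_config()].
#' @param date Date (or ISO string) to assemble for; must be on or after the
#'   first version's effective date.
#' @return An object of class `sentry_ruleset` with tibbles `keywords`
#'   (raw, normalized, sex_scope, effective_from, source_tag, matcher) and
#'   `codes`, the `as_of` date, and `match_descriptions` flag.
#' @export
assemble_ruleset_as_of <- function(versions, date) {
  date <- parse_date(as.character(date))
  eff <- as.Date(map_chr(versions, function(v) as.character(v$effective_from)))
  if (date < min(eff)) {
    abort(sprintf(
      "ruleset not yet defined: %s is before the first version (%s)",
      format(date), format(min(eff))
    ))
  }
  kw <- empty_keywords()
  cd <- empty_codes()
  collapsed <- 0L
  for (v in versions[eff <= date]) {
    if (nrow(v$add_keywords)) {
      add <- mutate(v$add_keywords,
        normalized = normalize_keyword(.data$raw),
        effective_from = v$effective_from,
        source_tag = v$version_id
      )
      dup <- paste(add$normalized, add$sex_scope) %in% paste(kw$normalized, kw$sex_scope) |
        duplicated(paste(add$normalized, add$sex_scope))
      collapsed <- collapsed + sum(dup)
      kw <- bind_rows(kw, add[!dup, names(kw)])
    }
    if (nrow(v$remove_keywords)) {
      rm_key <- paste(normalize_keyword(v$remove_keywords$raw), v$remove_keywords$sex_scope)
      missing_rm <- setdiff(rm_key, paste(kw$normalized, kw$sex_scope))
      if (length(missing_rm)) {
        abort(sprintf(
          "version %s removes pattern(s) not active at %s: %s",
          v$version_id, format(v$effective_from),
          paste(missing_rm, collapse = "; ")
        ))
      }
      kw <- kw[!paste(kw$normalized, kw$sex_scope) %in% rm_key, ]
    }
    if (nrow(v$add_codes)) {
      add <- mutate(v$add_codes,
        normalized = normalize_code(.data$raw_code),
        effective_from = v$effective_from
      )
      dup <- add$normalized %in% cd$normalized | duplicated(add$normalized)
      collapsed <- collapsed + sum(dup)
      cd <- bind_rows(cd, add[!dup, names(cd)])
    }
    if (nrow(v$remove_codes)) {
      rm_norm <- normalize_code(v$remove_codes$raw_code)
      missing_rm <- setdiff(rm_norm, cd$normalized)
      if (length(missing_rm)) {
        abort(sprintf(
          "version %s removes code(s) not active at %s: %s",
          v$version_id, format(v$effective_from),
          paste(missing_rm, collapse = "; ")
        ))
      }
      cd <- cd[!cd$normalized %in% rm_norm, ]
    }
  }
  kw$matcher <- lapply(kw$raw, compile_keyword)
  kw$n_tokens <- map_int(kw$matcher, function(m) length(m$tokens))
  kw$has_wild <- grepl("%", kw$normalized, fixed = TRUE)
  # code descriptions compiled as key phrases (used when match_descriptions)
  cd$desc_matcher <- lapply(cd$description, function(d) {
    if (nzchar(d) && grepl("[[:alnum:]]", d)) compile_keyword(d) else NULL
  })
  desc_from <- attr(versions, "match_code_descriptions_from")
  structure(
    list(
      as_of = date,
      keywords = kw,
      codes = cd,
      match_descriptions = isTRUE(!is.na(desc_from) && date >= desc_from)
    ),
    class = "sentry_ruleset",
    collapsed_duplicates = collapsed
  )
}

#' @export
print.sentry_ruleset <- function(x, ...) {
  cat(sprintf(
    "<sentry_ruleset> as of %s: %d keyword pattern(s), %d code pattern(s)%s\n",
    format(x$as_of), nrow(x$keywords), nrow(x$codes),
    if (x$match_descriptions) ", code descriptions matched as phrases" else ""
  ))
  invisible(x)
}

#' Diff two assembled rulesets
#'
#' Structured delta between two [assemble_ruleset_as_of()] results, keyed by
#' (normalized pattern, sex scope) for keywords and normalized code for
#' codes. `diff_rulesets(a, a)` is empty, and additions in `diff(a, b)`
#' equal removals in `diff(b, a)`.
#'
#' @param a,b `sentry_ruleset` objects.
#' @return A list of four tibbles: `keywords_added`, `keywords_removed`,
#'   `codes_added`, `codes_removed`.
#' @export
diff_rulesets <- function(a, b) {
  ka <- paste(a$keywords$normalized, a$keywords$sex_scope)
  kb <- paste(b$keywords$normalized, b$keywords$sex_scope)
  ca <- a$codes$normalized
  cb <- b$codes$normalized
  kw_cols <- c("raw", "normalized", "sex_scope")
  cd_cols <- c("raw_code", "normalized", "match_mode")
  list(
    keywords_added = as_tibble(b$keywords[!kb %in% ka, kw_cols]),
    keywords_removed = as_tibble(a$keywords[!ka %in% kb, kw_cols]),
    codes_added = as_tibble(b$codes[!cb %in% ca, cd_cols]),
    codes_removed = as_tibble(a$codes[!ca %in% cb, cd_cols])
  )
}

#' Path to the packaged default ruleset configuration
#'
#' @return Filesystem path to the YAML transcription of the published
#'   quarterly keyword/ICD-10 phenotype history shipped with the package.
#' @export
default_ruleset_path <- function() {
  system.file("extdata", "table1_default.yaml", package = "sentryr", mustWork = TRUE)
}
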