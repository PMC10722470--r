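#' @importFrom rlang %||% .data abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange bind_rows filter group_by left_join mutate n
#'   summarise ungroup distinct
#' @importFrom purrr map map_chr map_int map_lgl map2 pmap
NULL

# Half-up decimal rounding; base round() is round-half-even, which would turn
# e.g. 43.165 into 43.16 instead of the 43.17 convention used in reports.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# 32-bit FNV-1a over a string, returned as 8 hex characters. Used for
# reproducible alert identifiers; collision resistance beyond a single run
# is not required.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 2166136261
  for (b in bytes) {
    # xor with a byte only touches the low 8 bits, keeping h a double
    # (bitwXor cannot take values above .Machine$integer.max)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # multiply mod 2^32: split h to keep the double product exact
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- ((hi * 16777619) %% 65536) * 65536 + lo * 16777619
    h <- h %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# ISO-8601 timestamp handling: parse anything lubridate recognises, compare
# and store in UTC, serialize to the second.
parse_utc <- function(x) {
  out <- lubridate::ymd_hms(x, tz = "UTC", quiet = TRUE)
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    abort(sprintf(
      "unparseable ISO-8601 timestamp(s): %s",
      paste(unique(x[bad]), collapse = ", ")
    ))
  }
  out
}

format_utc <- function(x) {
  format(lubridate::with_tz(x, "UTC"), "%Y-%m-%dT%H:%M:%SZ")
}

parse_date <- function(x) {
  out <- as.Date(lubridate::ymd(x, quiet = TRUE))
  if (any(is.na(out) & !is.na(x))) {
    abort(sprintf("unparseable ISO date(s): %s", paste(x[is.na(out)], collapse = ", ")))
  }
  out
}

month_key <- function(t) format(lubridate::with_tz(t, "UTC"), "%Y-%m")

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("seed must be a single integer")
  }
  if (seed < 0) abort("seed must be non-negative")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
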