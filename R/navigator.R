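#' Navigator capacity model
#'
#' A High-Risk Patient Navigator (HRPN) reviews alerts subject to a monthly
#' review budget; months fully diverted to other duties (e.g. pandemic
#' response) get capacity 0. Whether a reviewed case is labeled "highly
#' suspicious" was a subjective navigator determination, modeled here as a
#' Bernoulli draw with probability `suspicion_rate`.
#'
#' @param navigator_id Identifier string.
#' @param monthly_capacity Named numeric vector mapping `"YYYY-MM"` to the
#'   maximum number of reviews that month (0 allowed).
#' @param suspicion_rate Probability in \[0, 1\] that a reviewed alert is
#'   labeled highly suspicious.
#' @param default_monthly Capacity for months absent from
#'   `monthly_capacity`; defaults to `Inf` (unconstrained).
#' @param contact_rate Probability that direct contact is made on review
#'   (recorded but feeding no funnel metric); default 0.5.
#' @return A list of class `navigator_capacity`.
#' @export
navigator_capacity <- function(navigator_id = "hrpn-1",
                               monthly_capacity = numeric(),
                               suspicion_rate = 0.24,
                               default_monthly = Inf,
                               contact_rate = 0.5) {
  if (length(monthly_capacity)) {
    if (is.null(names(monthly_capacity)) ||
      !all(grepl("^\\d{4}-\\d{2}$", names(monthly_capacity)))) {
      abort("monthly_capacity must be named with YYYY-MM keys")
    }
    if (any(monthly_capacity < 0)) abort("capacities must be >= 0")
  }
  if (suspicion_rate < 0 || suspicion_rate > 1) {
    abort("suspicion_rate must be in [0, 1]")
  }
  if (contact_rate < 0 || contact_rate > 1) abort("contact_rate must be in [0, 1]")
  if (default_monthly < 0) abort("default_monthly must be >= 0")
  structure(
    list(
      navigator_id = navigator_id,
      monthly_capacity = monthly_capacity,
      suspicion_rate = suspicion_rate,
      default_monthly = default_monthly,
      contact_rate = contact_rate
    ),
    class = "navigator_capacity"
  )
}

#' Read a navigator capacity file
#'
#' YAML with `navigator_id`, `suspicion_rate`, optional `default_monthly`
#' and `contact_rate`, and a `monthly:` map of `YYYY-MM: integer`.
#'
#' @param path Path to the YAML file.
#' @return A [navigator_capacity()] object.
#' @export
read_capacity_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  monthly <- unlist(cfg$monthly %||% list())
  navigator_capacity(
    navigator_id = cfg$navigator_id %||% "hrpn-1",
    monthly_capacity = monthly,
    suspicion_rate = cfg$suspicion_rate %||% 0.24,
    default_monthly = cfg$default_monthly %||% Inf,
    contact_rate = cfg$contact_rate %||% 0.5
  )
}

month_capacity <- function(capacity, month) {
  if (month %in% names(capacity$monthly_capacity)) {
    capacity$monthly_capacity[[month]]
  } else {
    capacity$default_monthly
  }
}

empty_outcomes <- function() {
  tibble(
    alert_id = character(), navigator_id = character(),
    reviewed_at = as.POSIXct(character(), tz = "UTC"),
    disposition = character(), contact_made = logical()
  )
}

#' Simulate capacity-limited navigator screening
#'
#' Replays the alert queue month by month: within each calendar month,
#' alerts are reviewed earliest-fired-first until the navigator's monthly
#' capacity is exhausted; the remainder expire at month end and are never
#' back-filled. Each reviewed alert is labeled `highly_suspicious` with
#' probability `suspicion_rate` (seeded RNG, so runs are reproducible).
#' Repeat alerts (`is_repeat`) for a patient already reviewed are routed to
#' the navigator who made the patient's first review — longitudinal
#' navigator affinity — and consume that navigator's capacity.
#'
#' @param alerts An alert tibble (see [run_batch()]), time-ordered or not
#'   (it is ordered internally by `fired_at`).
#' @param capacity A [navigator_capacity()], or a list of them: alerts go to
#'   the first navigator with remaining capacity except where patient
#'   affinity dictates otherwise.
#' @param seed Single non-negative integer seeding the review RNG.
#' @return A tibble of screening outcomes (`alert_id`, `navigator_id`,
#'   `reviewed_at`, `disposition`, `contact_made`), at most one row per
#'   alert.
#' @export
simulate_screening <- function(alerts, capacity, seed = 1L) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0) {
    abort("seed must be a single non-negative integer")
  }
  navs <- if (inherits(capacity, "navigator_capacity")) list(capacity) else capacity
  stopifnot(all(vapply(navs, inherits, logical(1), "navigator_capacity")))
  if (!nrow(alerts)) {
    return(empty_outcomes())
  }

  with_seed(seed, {
    alerts <- arrange(alerts, .data$fired_at, .data$alert_id)
    months <- month_key(alerts$fired_at)
    affinity <- character() # patient_id -> navigator_id of first review
    out <- list()
    for (mo in unique(months)) {
      remaining <- vapply(navs, month_capacity, numeric(1), month = mo)
      names(remaining) <- vapply(navs, function(n) n$navigator_id, character(1))
      idx <- which(months == mo)
      for (i in idx) {
        pid <- alerts$patient_id[i]
        nav_id <- if (pid %in% names(affinity)) {
          affinity[[pid]] # affinity is strict: only this navigator may review
        } else {
          open <- names(remaining)[remaining >= 1]
          if (length(open)) open[1] else NA_character_
        }
        if (is.na(nav_id) || remaining[[nav_id]] < 1) next # expires
        remaining[[nav_id]] <- remaining[[nav_id]] - 1
        if (!pid %in% names(affinity)) affinity[[pid]] <- nav_id
        nav <- navs[[match(nav_id, names(remaining))]]
        out[[length(out) + 1L]] <- tibble(
          alert_id = alerts$alert_id[i],
          navigator_id = nav_id,
          reviewed_at = alerts$fired_at[i],
          disposition = if (stats::runif(1) < nav$suspicion_rate) {
            "highly_suspicious"
          } else {
            "not_suspicious"
          },
          contact_made = stats::runif(1) < nav$contact_rate
        )
      }
    }
    if (length(out)) bind_rows(out) else empty_outcomes()
  })
}

#' Mark alerts screened or expired
#'
#' Sets each alert's `status` from a screening outcome table: `screened` if
#' an outcome exists for it, otherwise `expired` (the monthly queue is never
#' back-filled).
#'
#' @param alerts An alert tibble.
#' @param outcomes A [simulate_screening()] result.
#' @return `alerts` with `status` updated.
#' @export
apply_outcomes <- function(alerts, outcomes) {
  mutate(alerts, status = ifelse(
    .data$alert_id %in% outcomes$alert_id, "screened", "expired"
  ))
}
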