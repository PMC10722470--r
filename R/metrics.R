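#' Build a funnel summary from integer counts
#'
#' The reporting funnel is alerts -> screened -> "highly suspicious". Given
#' per-period integer counts this computes the two percentages — % of alerts
#' screened and % of screened alerts labeled highly suspicious (the
#' screened-in rate) — rounded half-up to 2 decimals, and appends a Total
#' row whose percentages are recomputed from the summed integers (never
#' averaged across periods). Percentages with a zero denominator are `NA`.
#'
#' @param period_label Character vector of period names.
#' @param n_alerts,n_screened,n_suspicious Integer vectors, one value per
#'   period; each level of the funnel can only shrink.
#' @param total Logical; append the Total row (default TRUE).
#' @return A tibble with columns `period_label`, `n_alerts`, `n_screened`,
#'   `pct_screened`, `n_suspicious`, `pct_screened_in`.
#' @examples
#' funnel_from_counts(
#'   c("Sep-Dec 2019", "2020", "Jan-Jul 2021"),
#'   n_alerts = c(276, 838, 649),
#'   n_screened = c(94, 325, 342),
#'   n_suspicious = c(30, 71, 83)
#' )
#' @export
funnel_from_counts <- function(period_label, n_alerts, n_screened,
                               n_suspicious, total = TRUE) {
  stopifnot(
    length(n_alerts) == length(period_label),
    length(n_screened) == length(period_label),
    length(n_suspicious) == length(period_label)
  )
  if (any(n_screened > n_alerts)) abort("n_screened cannot exceed n_alerts")
  if (any(n_suspicious > n_screened)) abort("n_suspicious cannot exceed n_screened")
  if (total && length(period_label)) {
    period_label <- c(period_label, "Total")
    n_alerts <- c(n_alerts, sum(n_alerts))
    n_screened <- c(n_screened, sum(n_screened))
    n_suspicious <- c(n_suspicious, sum(n_suspicious))
  }
  tibble(
    period_label = period_label,
    n_alerts = as.integer(n_alerts),
    n_screened = as.integer(n_screened),
    pct_screened = ifelse(
      n_alerts > 0, round_half_up(100 * n_screened / n_alerts, 2), NA_real_
    ),
    n_suspicious = as.integer(n_suspicious),
    pct_screened_in = ifelse(
      n_screened > 0, round_half_up(100 * n_suspicious / n_screened, 2), NA_real_
    )
  )
}

#' Summarize alerts and outcomes into the period funnel
#'
#' Buckets alerts into the supplied reporting periods by their fired date,
#' counts how many were screened (have an outcome) and how many of those
#' were labeled highly suspicious, and delegates to [funnel_from_counts()]
#' for the percentages and Total row. Periods must not overlap and must
#' cover every alert; an alert outside all periods is an error (listing the
#' offenders), not a silent drop.
#'
#' @param alerts Alert tibble.
#' @param outcomes Screening outcome tibble.
#' @param periods Tibble/data.frame with columns `label`, `start_date`,
#'   `end_date` (inclusive ISO dates or Dates).
#' @param total Logical; append the Total row.
#' @return A period-funnel tibble as in [funnel_from_counts()].
#' @export
summarize_funnel <- function(alerts, outcomes, periods, total = TRUE) {
  periods <- as_tibble(periods)
  stopifnot(all(c("label", "start_date", "end_date") %in% names(periods)))
  periods$start_date <- parse_date(as.character(periods$start_date))
  periods$end_date <- parse_date(as.character(periods$end_date))
  if (any(periods$end_date < periods$start_date)) {
    abort("period end_date before start_date")
  }
  p <- periods[order(periods$start_date), ]
  if (nrow(p) > 1 && any(p$start_date[-1] <= p$end_date[-nrow(p)])) {
    abort("periods overlap")
  }

  day <- as.Date(alerts$fired_at, tz = "UTC")
  bucket <- rep(NA_integer_, length(day))
  for (k in seq_len(nrow(periods))) {
    bucket[day >= periods$start_date[k] & day <= periods$end_date[k]] <- k
  }
  if (anyNA(bucket) && nrow(alerts)) {
    stray <- alerts$alert_id[is.na(bucket)]
    abort(sprintf(
      "alert(s) outside all periods: %s",
      paste(utils::head(stray, 10), collapse = ", ")
    ))
  }

  suspicious_ids <- outcomes$alert_id[outcomes$disposition == "highly_suspicious"]
  n_alerts <- n_screened <- n_suspicious <- integer(nrow(periods))
  for (k in seq_len(nrow(periods))) {
    ids <- alerts$alert_id[which(bucket == k)]
    n_alerts[k] <- length(ids)
    n_screened[k] <- sum(ids %in% outcomes$alert_id)
    n_suspicious[k] <- sum(ids %in% suspicious_ids)
  }
  funnel_from_counts(periods$label, n_alerts, n_screened, n_suspicious,
    total = total
  )
}

#' Monthly reviewed / highly-suspicious series
#'
#' Per-calendar-month counts of alerts reviewed and of reviewed alerts
#' labeled highly suspicious (the two monthly bar-chart series). Months with
#' no activity between the first and last alert month are present with
#' zeros, and the column sums equal the Total funnel integers.
#'
#' @param alerts Alert tibble.
#' @param outcomes Screening outcome tibble.
#' @return A tibble with columns `month` (`"YYYY-MM"`), `n_reviewed`,
#'   `n_suspicious`; zero rows for empty input.
#' @export
monthly_series <- function(alerts, outcomes) {
  if (!nrow(alerts)) {
    return(tibble(
      month = character(), n_reviewed = integer(), n_suspicious = integer()
    ))
  }
  mo <- month_key(alerts$fired_at)
  first <- min(as.Date(paste0(mo, "-01")))
  last <- max(as.Date(paste0(mo, "-01")))
  all_months <- format(seq(first, last, by = "month"), "%Y-%m")
  suspicious_ids <- outcomes$alert_id[outcomes$disposition == "highly_suspicious"]
  tibble(
    month = all_months,
    n_reviewed = vapply(all_months, function(m) {
      sum(alerts$alert_id[mo == m] %in% outcomes$alert_id)
    }, integer(1), USE.NAMES = FALSE),
    n_suspicious = vapply(all_months, function(m) {
      sum(alerts$alert_id[mo == m] %in% suspicious_ids)
    }, integer(1), USE.NAMES = FALSE)
  )
}

#' Annualized detection relative to a pre-program baseline
#'
#' Compares the program's highly-suspicious yield, annualized over the
#' observation window, to the number of possible cases identified per year
#' before the program: `(12 * total_suspicious / observation_months) /
#' baseline_per_year`.
#'
#' @param total_suspicious Total highly-suspicious cases observed.
#' @param baseline_per_year Pre-program possible cases per year (> 0).
#' @param observation_months Length of the observation window in months.
#' @return The detection ratio (1 = parity with baseline).
#' @examples
#' baseline_comparison(184, 10, 23) # 9.6
#' @export
baseline_comparison <- function(total_suspicious, baseline_per_year,
                                observation_months) {
  if (baseline_per_year <= 0) abort("baseline_per_year must be positive")
  if (observation_months <= 0) abort("observation_months must be positive")
  if (total_suspicious < 0) abort("total_suspicious must be non-negative")
  (12 * total_suspicious / observation_months) / baseline_per_year
}
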