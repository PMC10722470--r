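# Build a synthetic alert queue directly (screening only looks at ids,
# patients, and fire times).
mk_alerts <- function(n, months, patients = sprintf("P%d", seq_len(n))) {
  stopifnot(length(months) == n || length(months) == 1)
  fired <- as.POSIXct(paste0(rep_len(months, n), "-15 12:00:00"), tz = "UTC") +
    seq_len(n) # strictly increasing within a month
  tibble::tibble(
    alert_id = sprintf("A%04d", seq_len(n)),
    encounter_id = sprintf("E%04d", seq_len(n)),
    patient_id = patients,
    fired_at = fired,
    is_repeat = FALSE,
    status = "pending",
    evidence = replicate(n, tibble::tibble(), simplify = FALSE)
  )
}

test_that("monthly capacity caps reviews earliest-first; zero months review nothing", {
  alerts <- mk_alerts(10, c(rep("2020-08", 6), rep("2020-09", 4)))
  cap <- navigator_capacity(
    monthly_capacity = c("2020-08" = 4, "2020-09" = 0),
    suspicion_rate = 1.0
  )
  out <- simulate_screening(alerts, cap, seed = 3)
  expect_equal(nrow(out), 4L)
  # earliest four August alerts, none from the zero-capacity September
  expect_equal(sort(out$alert_id), alerts$alert_id[1:4])
  expect_true(all(out$reviewed_at >= alerts$fired_at[match(out$alert_id, alerts$alert_id)]))

  marked <- apply_outcomes(alerts, out)
  expect_equal(sum(marked$status == "screened"), 4L)
  expect_equal(sum(marked$status == "expired"), 6L)
})

test_that("saturation: unconstrained capacity with suspicion 1 screens everything in", {
  alerts <- mk_alerts(25, "2020-03")
  out <- simulate_screening(alerts, navigator_capacity(suspicion_rate = 1.0), seed = 1)
  expect_equal(nrow(out), 25L)
  expect_true(all(out$disposition == "highly_suspicious"))
  out0 <- simulate_screening(alerts, navigator_capacity(suspicion_rate = 0), seed = 1)
  expect_true(all(out0$disposition == "not_suspicious"))
})

test_that("suspicion draws track the configured rate (binomial check)", {
  alerts <- mk_alerts(1000, "2020-05")
  out <- simulate_screening(alerts, navigator_capacity(suspicion_rate = 0.24), seed = 9)
  frac <- mean(out$disposition == "highly_suspicious")
  se <- sqrt(0.24 * 0.76 / 1000)
  expect_lt(abs(frac - 0.24), 3 * se)
})

test_that("screening is seed-deterministic and conserves the funnel", {
  alerts <- mk_alerts(50, c(rep("2020-01", 30), rep("2020-02", 20)))
  cap <- navigator_capacity(
    monthly_capacity = c("2020-01" = 12, "2020-02" = 40),
    suspicion_rate = 0.3
  )
  o1 <- simulate_screening(alerts, cap, seed = 5)
  o2 <- simulate_screening(alerts, cap, seed = 5)
  expect_identical(o1, o2)
  o3 <- simulate_screening(alerts, cap, seed = 6)
  expect_false(identical(o1$disposition, o3$disposition))

  expect_lte(nrow(o1), nrow(alerts))
  expect_lte(sum(o1$disposition == "highly_suspicious"), nrow(o1))
  expect_error(simulate_screening(alerts, cap, seed = -1), "seed")
})

test_that("repeat alerts keep the patient's first navigator (affinity)", {
  # same patient alerts across months; two navigators with alternating
  # availability
  alerts <- mk_alerts(6, c("2020-01", "2020-01", "2020-02", "2020-02", "2020-03", "2020-03"),
    patients = c("P1", "P2", "P1", "P2", "P1", "P2")
  )
  navs <- list(
    navigator_capacity("nav-a",
      monthly_capacity = c("2020-02" = 0),
      suspicion_rate = 0.5
    ),
    navigator_capacity("nav-b", suspicion_rate = 0.5)
  )
  out <- simulate_screening(alerts, navs, seed = 2)
  per_patient <- tapply(out$navigator_id, alerts$patient_id[match(out$alert_id, alerts$alert_id)], unique)
  expect_true(all(lengths(per_patient) == 1L))
  # P1 and P2 were first reviewed by nav-a in January, so their February
  # alerts expire rather than switch navigators (strict affinity)
  expect_false(any(format(out$reviewed_at, "%m") == "02"))
})

test_that("capacity files round-trip through YAML", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "navigator_id: hrpn-1",
    "suspicion_rate: 0.24",
    "default_monthly: 30",
    "monthly:",
    "  2020-09: 0",
    "  2020-10: 25"
  ), p)
  cap <- read_capacity_config(p)
  expect_equal(cap$suspicion_rate, 0.24)
  expect_equal(cap$monthly_capacity[["2020-09"]], 0)
  expect_equal(cap$default_monthly, 30)
  expect_error(navigator_capacity(suspicion_rate = 1.2), "suspicion_rate")
  expect_error(navigator_capacity(monthly_capacity = c("2020-9" = 3)), "YYYY-MM")
})
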