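v_hist <- default_versions()

test_that("keyword, code-prefix, and description evidence fire as specified", {
  rules <- assemble_ruleset_as_of(v_hist, "2019-10-01")

  a <- scan_encounter(
    mk_enc(note_texts = "pt discloses forced labor situation", time = "2019-10-05T10:00:00Z"),
    rules
  )
  ev <- a$evidence[[1]]
  expect_setequal(
    ev$pattern_raw[ev$source == "note_text"],
    c("force%", "forced labor")
  )
  # spans re-extract to their matched text and re-match their pattern
  note <- "pt discloses forced labor situation"
  for (i in which(ev$source == "note_text")) {
    frag <- substr(note, ev$span_start[i] + 1, ev$span_end[i])
    expect_equal(frag, ev$matched_text[i])
    expect_true(keyword_matches(compile_keyword(ev$pattern_raw[i]), frag))
  }

  b <- scan_encounter(
    mk_enc(codes = "T74.21XA", time = "2019-10-05T10:00:00Z"),
    rules
  )
  evb <- b$evidence[[1]]
  expect_true(any(evb$source == "diagnosis_code" & evb$pattern_raw == "T74.21"))

  # no signal, no alert
  expect_null(scan_encounter(
    mk_enc(note_texts = "routine visit, no concerns", time = "2019-10-05T10:00:00Z"),
    rules
  ))
})

test_that("sex scoping: male encounters ignore female-scoped phrases and vice versa", {
  rules <- assemble_ruleset_as_of(v_hist, "2020-06-30")
  expect_null(scan_encounter(
    mk_enc(sex = "male", note_texts = "black eye noted on exam"), rules
  ))
  expect_false(is.null(scan_encounter(
    mk_enc(sex = "female", note_texts = "black eye noted on exam"), rules
  )))
  # unknown sex receives the union of all scopes
  expect_false(is.null(scan_encounter(
    mk_enc(sex = "unknown", note_texts = "black eye noted on exam"), rules
  )))
  expect_false(is.null(scan_encounter(
    mk_enc(sex = "male", note_texts = "testicular pain"), rules
  )))
  expect_null(scan_encounter(
    mk_enc(sex = "female", note_texts = "testicular pain"), rules
  ))
})

test_that("code descriptions match as key phrases once simplification is active", {
  enc <- mk_enc(
    codes = "X99.9",
    code_descs = "encounter for examination and observation of victim following forced sexual exploitation",
    time = "2019-10-05T10:00:00Z"
  )
  on_rules <- assemble_ruleset_as_of(v_hist, "2019-10-05")
  a <- scan_encounter(enc, on_rules)
  expect_true(any(a$evidence[[1]]$source == "diagnosis_description"))

  off_rules <- assemble_ruleset_as_of(v_hist, "2019-09-01") # before the flag date
  expect_null(scan_encounter(enc, off_rules))
})

test_that("ED utilization threshold fires after repeated visits in window", {
  cfg <- sentry_config(utilization_threshold = 3, utilization_window_days = 90)
  hist <- new_alert_history()
  times <- c("2020-02-01T10:00:00Z", "2020-02-10T10:00:00Z", "2020-02-20T10:00:00Z")
  alerts <- list()
  for (i in seq_along(times)) {
    res <- run_batch(
      mk_enc(sprintf("E%d", i), "P1", times[i], note_texts = "routine visit"),
      v_hist,
      batch_time = times[i], history = hist, config = cfg, batch_minutes = 15
    )
    hist <- res$history
    if (nrow(res$alerts)) alerts[[length(alerts) + 1]] <- res$alerts
  }
  alerts <- dplyr::bind_rows(alerts)
  expect_equal(nrow(alerts), 1L) # only the third visit trips the threshold
  expect_equal(alerts$encounter_id, "E3")
  expect_equal(alerts$evidence[[1]]$source, "utilization")
  expect_match(alerts$evidence[[1]]$matched_text, "3 ED visits")
})

test_that("batches are deterministic, idempotent, and re-alert repeat patients", {
  rules_time <- "2020-06-30T12:00:00Z"
  batch <- dplyr::bind_rows(
    mk_enc("E1", "P1", "2020-06-30T11:50:00Z", note_texts = "pt reports rape last month"),
    mk_enc("E2", "P2", "2020-06-30T11:55:00Z", note_texts = "routine follow up"),
    mk_enc("E3", "P3", "2020-06-30T11:58:00Z", note_texts = "migrant farm worker housing")
  )
  r1 <- run_batch(batch, v_hist, rules_time)
  r2 <- run_batch(batch, v_hist, rules_time)
  expect_equal(nrow(r1$alerts), 2L)
  expect_equal(r1$alerts$encounter_id, c("E1", "E3")) # encounter_id order
  expect_identical(r1$alerts$alert_id, r2$alerts$alert_id) # determinism

  # idempotence: re-running with the updated history adds nothing
  r3 <- run_batch(batch, v_hist, rules_time, history = r1$history)
  expect_equal(nrow(r3$alerts), 0L)

  # second visit of an alerted patient alerts even without a pattern hit
  later <- mk_enc("E9", "P1", "2020-07-10T09:00:00Z", note_texts = "suture removal, healing well")
  r4 <- run_batch(later, v_hist, "2020-07-10T09:10:00Z", history = r1$history)
  expect_equal(nrow(r4$alerts), 1L)
  expect_true(r4$alerts$is_repeat)
  expect_true("longitudinal_followup" %in% r4$alerts$evidence[[1]]$pattern_raw)

  # and not when longitudinal re-alerting is disabled
  r5 <- run_batch(later, v_hist,
    batch_time = "2020-07-10T09:10:00Z",
    history = r1$history, config = sentry_config(longitudinal_realert = FALSE)
  )
  expect_equal(nrow(r5$alerts), 0L)
})

test_that("late-arriving encounters warn but are still scanned", {
  enc <- mk_enc("E1", "P1", "2020-06-29T08:00:00Z", note_texts = "pt reports rape")
  expect_warning(
    res <- run_batch(enc, v_hist, "2020-06-30T12:00:00Z"),
    "outside"
  )
  expect_equal(nrow(res$alerts), 1L)
})

test_that("retrospective scan reports sensitivity on labels, rejects unknown ids", {
  store <- dplyr::bind_rows(
    mk_enc("E1", "P1", "2020-02-01T10:00:00Z", note_texts = "suspected trafficking disclosed"),
    mk_enc("E2", "P2", "2020-02-02T10:00:00Z", note_texts = "trafficking concern raised"),
    mk_enc("E3", "P3", "2020-02-03T10:00:00Z", note_texts = "routine visit")
  )
  rep <- retrospective_scan(v_hist, "2020-08-01", store, labels = c("E1", "E2"))
  expect_equal(rep$sensitivity, 1.0)
  expect_true("traffic%" %in% rep$per_pattern$pattern_raw)
  expect_gte(sum(rep$per_pattern$n_encounters), rep$n_alerts)

  expect_error(
    retrospective_scan(v_hist, "2020-08-01", store, labels = c("E1", "E99")),
    "E99"
  )
  # no labels: sensitivity absent, not zero
  expect_null(retrospective_scan(v_hist, "2020-08-01", store)$sensitivity)
  expect_null(retrospective_scan(v_hist, "2020-08-01", store, labels = character())$sensitivity)
})

test_that("alert sets grow with the as-of date on an all-female store", {
  # the single historical removal is male-scoped, so a female cohort sees a
  # purely cumulative vocabulary
  cc <- cohort_config(
    start_date = "2020-02-01", end_date = "2020-02-10",
    daily_volume = 25, trigger_prevalence = 0.15,
    sex_mix = c(male = 0, female = 1, unknown = 0),
    repeat_visit_rate = 0, seed = 11
  )
  g <- generate_cohort(cc, assemble_ruleset_as_of(v_hist, "2019-08-01"))
  early <- retrospective_scan(v_hist, "2019-08-01", g$encounters)
  late <- retrospective_scan(v_hist, "2020-08-01", g$encounters)
  expect_true(all(early$alerted %in% late$alerted))
})

test_that("alert, outcome, and history streams round-trip through JSONL/JSON", {
  batch <- dplyr::bind_rows(
    mk_enc("E1", "P1", "2020-06-30T11:50:00Z", note_texts = "pt reports rape last month"),
    mk_enc("E2", "P2", "2020-06-30T11:55:00Z", codes = "T74.21XA")
  )
  res <- run_batch(batch, v_hist, "2020-06-30T12:00:00Z")
  p <- withr::local_tempfile(fileext = ".jsonl")
  write_alerts(res$alerts, p)
  back <- read_alerts(p)
  expect_equal(back$alert_id, res$alerts$alert_id)
  expect_equal(as.numeric(back$fired_at), as.numeric(res$alerts$fired_at))
  expect_equal(
    lapply(back$evidence, as.data.frame),
    lapply(res$alerts$evidence, as.data.frame)
  )

  out <- simulate_screening(res$alerts, navigator_capacity(suspicion_rate = 0.5), seed = 1)
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  write_outcomes(out, p2)
  expect_equal(as.data.frame(read_outcomes(p2)), as.data.frame(out))

  p3 <- withr::local_tempfile(fileext = ".json")
  write_history(res$history, p3)
  h <- read_history(p3)
  expect_setequal(h$alerted_patients, res$history$alerted_patients)
  expect_equal(h$ed_start, res$history$ed_start)
})
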