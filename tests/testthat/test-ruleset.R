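test_that("default config transcribes the quarterly history", {
  v <- default_versions()
  ids <- vapply(v, function(x) x$version_id, character(1))
  expect_true(all(c("2019Q3", "2019Q4", "2020Q1", "2020Q2", "2020Q4", "2021Q2") %in% ids))

  q2 <- v[[which(ids == "2020Q2")]]
  expect_setequal(
    q2$add_keywords$raw,
    c("rape", "raped", "rapped", "molestation", "molested")
  )
  q1 <- v[[which(ids == "2020Q1")]]
  expect_true(all(c("penis", "testic%") %in%
    q1$add_keywords$raw[q1$add_keywords$sex_scope == "male_only"]))
  expect_true("safe house" %in% v[[which(ids == "2021Q2")]]$add_keywords$raw)
  # mid-quarter printed date honored
  midq <- v[[which(vapply(v, function(x) {
    "Z91.41" %in% x$add_codes$raw_code
  }, logical(1)))]]
  expect_equal(midq$effective_from, as.Date("2019-07-22"))
})

test_that("config validation rejects broken histories", {
  write_cfg <- function(txt) {
    p <- withr::local_tempfile(fileext = ".yaml", .local_envir = parent.frame(2))
    writeLines(txt, p)
    p
  }
  expect_error(
    load_ruleset_config(write_cfg("versions: []")),
    "no versions"
  )
  expect_error(
    load_ruleset_config(write_cfg(c(
      "versions:",
      "  - {id: a, effective_from: '2019-01-01', add_keywords: [{pattern: abuse}]}",
      "  - {id: a, effective_from: '2019-02-01', add_keywords: [{pattern: trauma}]}"
    ))),
    "duplicate version_id"
  )
  expect_error(
    load_ruleset_config(write_cfg(c(
      "versions:",
      "  - {id: a, effective_from: '2019-01-01', add_keywords: [{pattern: abuse}]}",
      "  - {id: b, effective_from: '2019-02-01', remove_keywords: [{pattern: trauma}]}"
    ))),
    "not active"
  )
})

test_that("assembly honors effective dates with an inclusive boundary", {
  v <- default_versions()
  r_oct19 <- assemble_ruleset_as_of(v, "2019-10-01")
  expect_true("trauma" %in% r_oct19$keywords$normalized) # 2019Q3
  expect_false("rape" %in% r_oct19$keywords$normalized) # added 2020Q2
  # inclusive boundary: 2019Q4 additions active on 2019-10-01 itself
  expect_true("traffic%" %in% r_oct19$keywords$normalized)
  expect_false("traffic%" %in%
    assemble_ruleset_as_of(v, "2019-09-30")$keywords$normalized)

  expect_true("rape" %in% assemble_ruleset_as_of(v, "2020-04-01")$keywords$normalized)
  expect_error(assemble_ruleset_as_of(v, "2019-06-30"), "not yet defined")
})

test_that("male scope excludes 'black eye' from 2020Q1 on", {
  v <- default_versions()
  r <- assemble_ruleset_as_of(v, "2020-06-30")
  male_kw <- sentryr:::eligible_keywords(r$keywords, "male")
  female_kw <- sentryr:::eligible_keywords(r$keywords, "female")
  expect_false("black eye" %in% male_kw$normalized)
  expect_true("black eye" %in% female_kw$normalized)
  expect_true("penis" %in% male_kw$normalized)
  expect_false("penis" %in% female_kw$normalized)
  # before the male list existed, black eye applied to everyone
  r_before <- assemble_ruleset_as_of(v, "2019-12-31")
  expect_true("black eye" %in%
    sentryr:::eligible_keywords(r_before$keywords, "male")$normalized)
})

test_that("duplicate listings collapse to one active pattern", {
  v <- default_versions()
  r <- assemble_ruleset_as_of(v, "2021-07-01")
  expect_equal(sum(r$codes$normalized == "Z9142"), 1L) # printed four times
  expect_equal(sum(r$keywords$normalized == "neglect"), 1L) # added twice
  expect_equal(anyDuplicated(paste(r$keywords$normalized, r$keywords$sex_scope)), 0L)
  expect_gt(attr(r, "collapsed_duplicates"), 0L)
})

test_that("assembly is idempotent and monotone between removals", {
  v <- default_versions()
  a <- assemble_ruleset_as_of(v, "2020-08-15")
  b <- assemble_ruleset_as_of(v, "2020-08-15")
  expect_identical(
    a$keywords[setdiff(names(a$keywords), "matcher")],
    b$keywords[setdiff(names(b$keywords), "matcher")]
  )
  expect_identical(a$codes$normalized, b$codes$normalized)

  # the only removal in the default history is at 2020-01-01; sets grow
  # within the spans on either side of it
  key <- function(r) paste(r$keywords$normalized, r$keywords$sex_scope)
  spans <- list(
    c("2019-07-01", "2019-08-01", "2019-10-01", "2019-12-31"),
    c("2020-01-01", "2020-04-01", "2020-10-01", "2021-04-01", "2021-07-31")
  )
  for (span in spans) {
    for (i in seq_len(length(span) - 1)) {
      d1 <- key(assemble_ruleset_as_of(v, span[i]))
      d2 <- key(assemble_ruleset_as_of(v, span[i + 1]))
      expect_true(all(d1 %in% d2), label = paste(span[i], "subset of", span[i + 1]))
    }
  }
})

test_that("ruleset diffs are empty on identity, inverse-symmetric, and apply", {
  v <- default_versions()
  a <- assemble_ruleset_as_of(v, "2019-10-01")
  b <- assemble_ruleset_as_of(v, "2020-07-01")

  d_aa <- diff_rulesets(a, a)
  expect_equal(nrow(d_aa$keywords_added), 0L)
  expect_equal(nrow(d_aa$keywords_removed), 0L)
  expect_equal(nrow(d_aa$codes_added), 0L)
  expect_equal(nrow(d_aa$codes_removed), 0L)

  d_ab <- diff_rulesets(a, b)
  d_ba <- diff_rulesets(b, a)
  expect_true("rape" %in% d_ab$keywords_added$normalized)
  key <- function(t) sort(paste(t$normalized, t$sex_scope))
  expect_equal(key(d_ab$keywords_added), key(d_ba$keywords_removed))
  expect_equal(key(d_ab$keywords_removed), key(d_ba$keywords_added))

  # applying the delta to a's key set yields b's key set
  ka <- paste(a$keywords$normalized, a$keywords$sex_scope)
  kb <- paste(b$keywords$normalized, b$keywords$sex_scope)
  applied <- union(
    setdiff(ka, paste(d_ab$keywords_removed$normalized, d_ab$keywords_removed$sex_scope)),
    paste(d_ab$keywords_added$normalized, d_ab$keywords_added$sex_scope)
  )
  expect_setequal(applied, kb)
})
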