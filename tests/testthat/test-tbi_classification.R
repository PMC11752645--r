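test_that("event severity follows the symptom-duration rules", {
  cases <- data.frame(
    loc     = c("lt30min", "na",    "na",   "min30_to_24h", "gt24h", "na",    "lt30min"),
    aoc     = c("lt24h",   "gt24h", "na",   "na",           "lt24h", "na",    "na"),
    amnesia = c("lt24h",   "na",    "na",   "lt24h",        "na",    "gt24h", "na"),
    expected = c("mild", "moderate_severe", "mild", "moderate_severe",
                 "moderate_severe", "moderate_severe", "mild"),
    stringsAsFactors = FALSE
  )
  ev <- tbi_events(period = "since", year = 1990, loc = cases$loc,
                   aoc = cases$aoc, amnesia = cases$amnesia)
  expect_identical(classify_event_severity(ev), cases$expected)
  expect_error(tbi_events(loc = "20min"), "loc")
})

test_that("subject status aggregates events: worst severity, count, lag, PET-date exclusion", {
  expect_identical(classify_subject_tbi(NULL)$history, "no")
  empty <- classify_subject_tbi(tbi_events()[0, ], 2018)
  expect_identical(empty$severity, "none")
  expect_identical(empty$frequency, 0L)

  ev <- tbi_events(period = c("during", "since", "since"),
                   year = c(1969, 1985, 2001),
                   loc = c("lt30min", "na", "gt24h"),
                   aoc = c("na", "lt24h", "na"))
  st <- classify_subject_tbi(ev, tau_pet_date = 2018.5)
  expect_identical(st$severity, "moderate_severe")
  expect_identical(st$frequency, 3L)
  expect_equal(st$last_event_lag, 2018.5 - 2001)
  expect_true(st$occurred_in_vietnam)

  # the only event postdates the tau-PET scan: excluded, history becomes no
  late <- tbi_events(period = "since", year = 2020, loc = "gt24h")
  st2 <- classify_subject_tbi(late, tau_pet_date = 2018.5)
  expect_identical(st2$history, "no")
  expect_identical(st2$frequency, 0L)
  # same event before an unknown scan date counts
  expect_identical(classify_subject_tbi(late, NA)$history, "yes")
})

test_that("adding an event never lowers severity or frequency", {
  sev_rank <- c(none = 0, mild = 1, moderate_severe = 2)
  set.seed(77)
  rand_events <- function(k) {
    if (k == 0) return(tbi_events()[0, ])
    tbi_events(period = "since",
               year = sample(1976:2010, k, replace = TRUE),
               loc = sample(c("na", "lt30min", "min30_to_24h", "gt24h"),
                            k, replace = TRUE),
               aoc = sample(c("na", "lt24h", "gt24h"), k, replace = TRUE))
  }
  for (rep in 1:25) {
    ev <- rand_events(sample(0:4, 1))
    extra <- tbi_events(period = "since", year = sample(1976:2010, 1),
                        loc = sample(c("na", "lt30min", "min30_to_24h", "gt24h"), 1),
                        aoc = sample(c("na", "lt24h", "gt24h"), 1))
    before <- classify_subject_tbi(ev, 2018)
    after <- classify_subject_tbi(rbind(ev, extra), 2018)
    expect_gte(sev_rank[[after$severity]], sev_rank[[before$severity]])
    expect_gte(after$frequency, before$frequency)
  }
})

test_that("reconciliation applies year-over-period precedence and logs every adjustment", {
  raw <- data.frame(
    period = c(NA, "during", "since", NA),
    year = c(1970, 1995, 2001, NA),
    age_at_event = c(25, NA, NA, 30),
    loc = c("lt30min", "na", "na", "gt24h"),
    aoc = c("na", "gt24h", "lt24h", "na"),
    amnesia = "na", stringsAsFactors = FALSE
  )
  rec <- reconcile_events(raw, birth_year = 1945)
  ev <- rec$events
  # row 1: dated, symptomatic, no period -> period inferred, event kept
  expect_identical(ev$period[1], "during")
  expect_identical(ev$status[1], "adjusted")
  # row 2: period contradicts year by decades -> year wins, period corrected
  expect_identical(ev$period[2], "since")
  expect_true(any(grepl("row 2.*corrected.*year 1995 wins", rec$log)))
  # row 3: fully consistent -> untouched, not logged
  expect_identical(ev$status[3], "kept")
  expect_false(any(grepl("row 3", rec$log)))
  # row 4: no year, but age + birth year -> year derived
  expect_equal(ev$year[4], 1975)
  expect_identical(ev$period[4], "during")

  st <- classify_subject_tbi(ev, 2018)
  expect_identical(st$frequency, 4L)
})

test_that("unresolvable rows are flagged, excluded from frequency, and logged", {
  raw <- data.frame(period = NA, year = NA, age_at_event = NA,
                    loc = "gt24h", aoc = "na", amnesia = "na",
                    stringsAsFactors = FALSE)
  rec <- reconcile_events(raw)
  expect_identical(rec$events$status, "unresolvable")
  expect_true(any(grepl("unresolvable", rec$log)))
  st <- classify_subject_tbi(rec$events, 2018)
  expect_identical(st$frequency, 0L)
  expect_error(reconcile_events(raw[, -1]), "missing column")
})

test_that("frequency counting reproduces a cohort histogram exactly", {
  counts <- rep(c(1L, 2L, 3L, 4L, 5L, 7L), c(35L, 15L, 11L, 1L, 2L, 1L))
  events <- lapply(counts, function(k)
    tbi_events(period = "since", year = seq(1980, by = 2, length.out = k),
               loc = "lt30min"))
  names(events) <- sprintf("T%02d", seq_along(events))
  status <- classify_cohort_tbi(events, 2018)
  tab <- tbi_frequency_table(status$frequency)
  expect_identical(tab$n_events, c(1L, 2L, 3L, 4L, 5L, 7L))
  expect_identical(tab$n_subjects, c(35L, 15L, 11L, 1L, 2L, 1L))
  expect_equal(tab$percent[1], 100 * 35 / 65)
  expect_equal(tab$percent[2], 100 * 15 / 65)
})
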