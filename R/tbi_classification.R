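#' @name tbi-classification
#' @title DoD/VA-guideline TBI severity classification
#' @description
#' Severity of a head-injury event is graded from three interview fields:
#' loss of consciousness (LOC: none recorded, 0-30 min, >30 min and <24 h,
#' >24 h), alteration of consciousness (AOC: none, <24 h, >24 h) and
#' post-traumatic amnesia (none, <24 h, >24 h). An event is
#' moderate/severe when at least one field falls into a moderate or severe
#' category (LOC >30 min, or AOC / amnesia >24 h), otherwise mild. The
#' amnesia moderate-vs-severe split (>1 day vs >7 days) is deliberately
#' not modelled: interview instruments commonly top-code at >1 day, so
#' moderate and severe are pooled into one bucket throughout.
NULL

.loc_levels <- c("na", "lt30min", "min30_to_24h", "gt24h")
.aoc_levels <- c("na", "lt24h", "gt24h")
.amnesia_levels <- .aoc_levels

#' Construct TBI event reports
#'
#' @param period reporting period of each event: `"before"`, `"during"`,
#'   `"since"` (relative to the subject's military service window),
#'   `"past_year"` or `"unspecified"`.
#' @param year calendar year of the event (NA allowed).
#' @param age_at_event subject age at the event in years (NA allowed).
#' @param loc loss-of-consciousness category: `"na"`, `"lt30min"`,
#'   `"min30_to_24h"`, `"gt24h"`.
#' @param aoc alteration-of-consciousness category: `"na"`, `"lt24h"`,
#'   `"gt24h"`.
#' @param amnesia post-traumatic amnesia category: `"na"`, `"lt24h"`,
#'   `"gt24h"`.
#' @return data.frame of class `tbi_events`, one row per event.
#' @export
tbi_events <- function(period = "unspecified", year = NA_real_,
                       age_at_event = NA_real_, loc = "na", aoc = "na",
                       amnesia = "na") {
  n <- max(length(period), length(year), length(age_at_event),
           length(loc), length(aoc), length(amnesia))
  out <- data.frame(
    period = rep_len(as.character(period), n),
    year = rep_len(as.numeric(year), n),
    age_at_event = rep_len(as.numeric(age_at_event), n),
    loc = rep_len(as.character(loc), n),
    aoc = rep_len(as.character(aoc), n),
    amnesia = rep_len(as.character(amnesia), n),
    stringsAsFactors = FALSE
  )
  bad_period <- !out$period %in% c("before", "during", "since", "past_year",
                                   "unspecified")
  if (any(bad_period))
    stop("tbi_events: unknown period value(s): ",
         paste(unique(out$period[bad_period]), collapse = ", "), call. = FALSE)
  for (f in c("loc", "aoc", "amnesia")) {
    lev <- switch(f, loc = .loc_levels, .aoc_levels)
    if (!all(out[[f]] %in% lev))
      stop(sprintf("tbi_events: invalid '%s' value(s)", f), call. = FALSE)
  }
  class(out) <- c("tbi_events", "data.frame")
  out
}

#' Classify the severity of a single TBI event
#'
#' Moderate/severe when any symptom reaches a moderate/severe duration
#' category (LOC longer than 30 min, or AOC or amnesia longer than 24 h);
#' otherwise mild — including events where every field is "na", because a
#' reported countable head injury with no qualifying symptom duration is
#' graded mild by the guideline's fallback.
#'
#' @param events a [tbi_events()] data.frame (or anything coercible).
#' @return character vector, `"mild"` or `"moderate_severe"` per event.
#' @export
classify_event_severity <- function(events) {
  modsev <- events$loc %in% c("min30_to_24h", "gt24h") |
    events$aoc == "gt24h" | events$amnesia == "gt24h"
  ifelse(modsev, "moderate_severe", "mild")
}

#' Classify a subject's overall TBI status
#'
#' Events dated after the tau-PET scan are excluded before anything else
#' is computed (head-injury information only counts when the event
#' precedes the PET measurement). Overall severity is the worst included
#' event severity, frequency the count of included events, and the lag the
#' time from the latest included event to the tau-PET date.
#'
#' @param events a [tbi_events()] data.frame; may have zero rows. A
#'   `status` column from [reconcile_events()] is honoured: rows flagged
#'   `"unresolvable"` are dropped before counting.
#' @param tau_pet_date tau-PET scan date as a decimal year (e.g. 2018.5).
#'   Events with `year > tau_pet_date` are excluded. Events without a year
#'   are assumed to precede the scan (interviews ask about past injuries).
#' @param service_window two-year span of military service, used to flag
#'   whether any event occurred during service.
#' @return one-row data.frame: `history` ("no"/"yes"), `severity`
#'   ("none"/"mild"/"moderate_severe"), `frequency`, `last_event_lag`
#'   (years, NA when no dated event), `occurred_in_vietnam`.
#' @export
classify_subject_tbi <- function(events, tau_pet_date = NA_real_,
                                 service_window = c(1964, 1975)) {
  if (!is.null(events) && !is.null(events$status))
    events <- events[events$status != "unresolvable", , drop = FALSE]
  if (is.null(events) || nrow(events) == 0L) {
    return(data.frame(history = "no", severity = "none", frequency = 0L,
                      last_event_lag = NA_real_, occurred_in_vietnam = FALSE,
                      stringsAsFactors = FALSE))
  }
  keep <- rep(TRUE, nrow(events))
  if (!is.na(tau_pet_date))
    keep <- is.na(events$year) | events$year <= tau_pet_date
  events <- events[keep, , drop = FALSE]
  if (nrow(events) == 0L)
    return(classify_subject_tbi(events[0, ], tau_pet_date))
  sev <- classify_event_severity(events)
  severity <- if (any(sev == "moderate_severe")) "moderate_severe" else "mild"
  lag <- NA_real_
  if (!is.na(tau_pet_date) && any(!is.na(events$year)))
    lag <- tau_pet_date - max(events$year, na.rm = TRUE)
  in_vietnam <- any(events$period == "during") ||
    any(!is.na(events$year) & events$year >= service_window[1] &
          events$year <= service_window[2])
  data.frame(history = "yes", severity = severity, frequency = nrow(events),
             last_event_lag = lag, occurred_in_vietnam = in_vietnam,
             stringsAsFactors = FALSE)
}

#' Reconcile raw interview rows into consistent TBI event reports
#'
#' Interview records can disagree internally: a dated, symptomatic event
#' with no reporting period, or a period that contradicts the stated year.
#' Reconciliation applies a deterministic precedence — explicit year >
#' year derived from age and birth year > period bucket — corrects the
#' period from the winning year, and logs every adjustment. Rows where no
#' timing information can be established at all are flagged
#' `"unresolvable"`, excluded from downstream frequency counts, and
#' logged; nothing is dropped silently.
#'
#' @param raw data.frame with columns `period`, `year`, `age_at_event`,
#'   `loc`, `aoc`, `amnesia` (missing values allowed in the first three).
#' @param birth_year subject birth year, used to derive an event year from
#'   `age_at_event` when `year` is missing.
#' @param service_window two-year span of military service used to map a
#'   year onto a period bucket (default 1964-1975).
#' @param interview_year interview date used for the `"past_year"` bucket.
#' @return list with `events` (a [tbi_events()] data.frame plus a `status`
#'   column: `"kept"`, `"adjusted"` or `"unresolvable"`) and `log`
#'   (character vector, one entry per adjustment).
#' @export
reconcile_events <- function(raw, birth_year = NA_real_,
                             service_window = c(1964, 1975),
                             interview_year = NA_real_) {
  need <- c("period", "year", "age_at_event", "loc", "aoc", "amnesia")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("reconcile_events: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  log <- character(0)
  status <- character(nrow(raw))
  period <- as.character(raw$period)
  period[is.na(period) | period == ""] <- "unspecified"
  year <- as.numeric(raw$year)

  period_from_year <- function(y) {
    if (!is.na(interview_year) && y >= interview_year - 1) "past_year"
    else if (y < service_window[1]) "before"
    else if (y <= service_window[2]) "during"
    else "since"
  }

  for (i in seq_len(nrow(raw))) {
    status[i] <- "kept"
    yr <- year[i]
    if (is.na(yr) && !is.na(raw$age_at_event[i]) && !is.na(birth_year)) {
      yr <- birth_year + raw$age_at_event[i]
      year[i] <- yr
      status[i] <- "adjusted"
      log <- c(log, sprintf("row %d: year %.0f derived from age %.0f and birth year %.0f",
                            i, yr, raw$age_at_event[i], birth_year))
    }
    if (!is.na(yr)) {
      implied <- period_from_year(yr)
      if (period[i] == "unspecified") {
        period[i] <- implied
        status[i] <- "adjusted"
        log <- c(log, sprintf("row %d: period inferred as '%s' from year %.0f",
                              i, implied, yr))
      } else if (period[i] != implied &&
                 !(period[i] == "past_year" && implied == "since")) {
        # explicit year outranks the reported period bucket
        log <- c(log, sprintf("row %d: period corrected '%s' -> '%s' (year %.0f wins)",
                              i, period[i], implied, yr))
        period[i] <- implied
        status[i] <- "adjusted"
      }
    } else if (period[i] == "unspecified") {
      status[i] <- "unresolvable"
      log <- c(log, sprintf("row %d: no period, year or usable age; flagged unresolvable", i))
    }
  }
  events <- tbi_events(period = period, year = year,
                       age_at_event = raw$age_at_event,
                       loc = raw$loc, aoc = raw$aoc, amnesia = raw$amnesia)
  events$status <- status
  list(events = events, log = log)
}

#' Tabulate per-subject TBI status for a cohort
#'
#' @param events_by_subject named list of [tbi_events()] data.frames (one
#'   per subject; empty/NULL for no reported injury).
#' @param tau_pet_dates named numeric vector of tau-PET dates (decimal
#'   years), or a single value recycled.
#' @return data.frame, one row per subject, as returned by
#'   [classify_subject_tbi()] plus a `subject_id` column.
#' @export
classify_cohort_tbi <- function(events_by_subject, tau_pet_dates = NA_real_) {
  ids <- names(events_by_subject)
  if (is.null(ids)) ids <- as.character(seq_along(events_by_subject))
  dates <- rep_len(tau_pet_dates, length(ids))
  if (!is.null(names(tau_pet_dates))) dates <- tau_pet_dates[ids]
  rows <- lapply(seq_along(ids), function(i)
    classify_subject_tbi(events_by_subject[[i]], dates[[i]]))
  out <- do.call(rbind, rows)
  cbind(data.frame(subject_id = ids, stringsAsFactors = FALSE), out)
}

#' TBI frequency histogram
#'
#' Counts subjects by number of TBI events, among subjects with at least
#' one event; proportions are relative to that TBI-positive subgroup.
#'
#' @param frequency integer vector of per-subject event counts.
#' @return data.frame with `n_events`, `n_subjects`, `percent`.
#' @export
tbi_frequency_table <- function(frequency) {
  frequency <- frequency[frequency > 0]
  tab <- table(frequency)
  data.frame(
    n_events = as.integer(names(tab)),
    n_subjects = as.integer(tab),
    percent = 100 * as.integer(tab) / length(frequency)
  )
}
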