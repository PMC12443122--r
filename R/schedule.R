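# Scheduler: expands a routine-anchored regimen into intended dose slots, each
# carrying its dosing window. The dosing window opens 1 h before the intended
# time and closes at intended time + safe window; membership is half-open
# [start, end) so every instant maps to exactly one state.

WINDOW_LEAD_HOURS <- 1        # the window opens this long before the intended time
SNOOZE_MINUTES <- 15          # a snooze re-reminds after this many minutes

#' Define a dosing regimen anchored to daily routines
#'
#' A regimen binds one formulary medication (at one frequency) to the clock
#' times a user actually takes it, e.g. `c(breakfast = "08:00")`. Anchor names
#' are routine labels and carry no semantics beyond documentation.
#'
#' @param medication Generic (or brand) name resolvable in the formulary.
#' @param frequency_per_day Doses per day; must be covered by the formulary.
#' @param anchor_times Character vector of `"HH:MM"` clock times, one per daily
#'   dose, strictly increasing within the day; optionally named by routine.
#' @param dose Optional per-component dose tuple (mg); checked against the
#'   entry's dose options when supplied.
#' @param timezone IANA zone name (patients follow wall clocks, so anchors are
#'   wall-clock times; a nonexistent time on a DST transition day resolves to
#'   the earliest valid instant).
#' @param start_date,end_date Calendar dates (anything `as.Date` accepts).
#' @return A `regimen` object.
#' @export
regimen <- function(medication, frequency_per_day, anchor_times, dose = NULL,
                    timezone = "UTC", start_date, end_date) {
  frequency_per_day <- as.integer(frequency_per_day)
  if (length(anchor_times) != frequency_per_day) {
    dw_abort(sprintf("regimen needs %d anchor time(s), got %d",
                     frequency_per_day, length(anchor_times)),
             "dosewindow_regimen_error")
  }
  mins <- vapply(anchor_times, parse_hhmm, integer(1))
  if (frequency_per_day > 1L && any(diff(mins) <= 0L)) {
    dw_abort("anchor times must be strictly increasing within the day",
             "dosewindow_regimen_error")
  }
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  structure(
    list(
      medication = canon_name(medication),
      frequency_per_day = frequency_per_day,
      anchor_times = anchor_times,
      anchor_minutes = mins,
      dose = if (!is.null(dose)) as.numeric(dose),
      timezone = timezone,
      start_date = start_date,
      end_date = end_date
    ),
    class = "regimen"
  )
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("<regimen> %s x%d/day at %s (%s), %s to %s\n",
              x$medication, x$frequency_per_day,
              paste(x$anchor_times, collapse = ", "), x$timezone,
              format(x$start_date), format(x$end_date)))
  invisible(x)
}

#' Expand a regimen into intended dose slots with dosing windows
#'
#' One slot per anchor time per calendar day in `[start_date, end_date]`,
#' strictly ordered by intended time. Each slot's window runs from 1 h before
#' the intended time to intended time + the medication's safe window. Windows
#' of consecutive slots must be disjoint, which requires consecutive intended
#' doses (including across midnight) to be separated by more than
#' `safe_window_hours + 1` h; a violation raises a classed `"windows-overlap"`
#' error. Regeneration for the same regimen is idempotent: slot ids and
#' timestamps are a pure function of the regimen and formulary entry.
#'
#' @param regimen A `regimen`.
#' @param formulary A validated `formulary`; the medication and dose must
#'   resolve ([lookup()] succeeds and, when the regimen carries a dose,
#'   [validate_dose()] is `TRUE`).
#' @return A `dose_slots` data frame with columns `slot_id`, `intended_time`,
#'   `window_start`, `window_end`; the resolved `medication_entry` and the
#'   regimen are attached as attributes.
#' @export
generate_slots <- function(regimen, formulary) {
  stopifnot(inherits(regimen, "regimen"))
  entry <- lookup(formulary, regimen$medication, regimen$frequency_per_day)
  if (!is.null(regimen$dose) && !validate_dose(entry, regimen$dose)) {
    dw_abort(sprintf("dose %s is not a listed option for %s",
                     fmt_dose_tuple(regimen$dose), entry$generic_name),
             "dosewindow_regimen_error")
  }
  if (regimen$end_date < regimen$start_date) {
    return(empty_slots(entry, regimen))
  }
  days <- seq(regimen$start_date, regimen$end_date, by = "day")
  intended <- .POSIXct(unlist(lapply(days, function(d) {
    vapply(regimen$anchor_minutes, function(m) {
      as.numeric(local_time(d, m, regimen$timezone))
    }, numeric(1))
  })), tz = regimen$timezone)
  sw <- entry$safe_window_hours
  if (length(intended) > 1L) {
    gaps <- diff(as.numeric(intended))
    if (any(gaps <= (sw + WINDOW_LEAD_HOURS) * 3600)) {
      i <- which(gaps <= (sw + WINDOW_LEAD_HOURS) * 3600)[1]
      dw_abort(sprintf(
        "windows-overlap: doses %d and %d are %.2f h apart; need more than %g h (safe window %g + lead %g)",
        i, i + 1L, gaps[i] / 3600, sw + WINDOW_LEAD_HOURS, sw, WINDOW_LEAD_HOURS),
        "dosewindow_windows_overlap_error")
    }
  }
  slots <- data.frame(
    slot_id = seq_along(intended),
    intended_time = intended,
    window_start = intended - WINDOW_LEAD_HOURS * 3600,
    window_end = intended + sw * 3600
  )
  attr(slots, "entry") <- entry
  attr(slots, "regimen") <- regimen
  class(slots) <- c("dose_slots", "data.frame")
  slots
}

empty_slots <- function(entry, regimen) {
  slots <- data.frame(
    slot_id = integer(),
    intended_time = .POSIXct(numeric(), tz = regimen$timezone),
    window_start = .POSIXct(numeric(), tz = regimen$timezone),
    window_end = .POSIXct(numeric(), tz = regimen$timezone)
  )
  attr(slots, "entry") <- entry
  attr(slots, "regimen") <- regimen
  class(slots) <- c("dose_slots", "data.frame")
  slots
}

slot_at <- function(slots, slot_id) {
  i <- match(slot_id, slots$slot_id)
  if (is.na(i)) {
    dw_abort(sprintf("unknown slot_id %s", slot_id), "dosewindow_not_found_error")
  }
  list(slot_id = slots$slot_id[i], intended_time = slots$intended_time[i],
       window_start = slots$window_start[i], window_end = slots$window_end[i])
}

#' The dosing window of a slot
#'
#' @param slot A single slot (one row of a `dose_slots` frame, or the list
#'   produced internally by the engine).
#' @return A `dose_window`: list with `start` and `end`, interpreted as the
#'   half-open interval `[start, end)`.
#' @export
window_for <- function(slot) {
  structure(list(start = slot$window_start[[1]], end = slot$window_end[[1]]),
            class = "dose_window")
}

#' @export
print.dose_window <- function(x, ...) {
  cat(sprintf("<dose_window> [%s, %s)\n", format(x$start), format(x$end)))
  invisible(x)
}

#' Half-open membership test for a dosing window
#'
#' Closed at the start, open at the end: the first in-window minute is exactly
#' 1 h before the intended time and the instant `intended + safe window` is
#' already out of the window.
#'
#' @param window A `dose_window` from [window_for()].
#' @param time POSIXct time(s).
#' @return Logical vector.
#' @export
in_window <- function(window, time) {
  as.numeric(time) >= as.numeric(window$start) & as.numeric(time) < as.numeric(window$end)
}
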