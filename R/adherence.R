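# Adherence summaries over an event log: partition the scheduled slots into
# taken on time / taken late / skipped / missed and derive rates. Feeds the
# kind of medication-taking visualization an adherence app presents.

#' Validate an event log against a slot schedule
#'
#' Checks that every event references a scheduled slot and that no slot
#' records more than one take (the engine's duplicate-dose safety guarantee;
#' a hand-written log violating it is rejected).
#'
#' @param log A data frame in the [events_to_df()] layout.
#' @param slots A `dose_slots` frame.
#' @return `TRUE`, invisibly; classed errors otherwise.
#' @export
validate_event_log <- function(log, slots) {
  unknown <- setdiff(unique(log$slot_id), slots$slot_id)
  if (length(unknown)) {
    dw_abort(sprintf("event log references unknown slot_id(s): %s",
                     paste(unknown, collapse = ", ")),
             "dosewindow_log_error")
  }
  takes <- log$slot_id[log$action %in% c("TAKE")]
  dup <- unique(takes[duplicated(takes)])
  if (length(dup)) {
    dw_abort(sprintf("duplicate take(s) on slot(s) %s: violates no-duplicate-dosing safety",
                     paste(dup, collapse = ", ")),
             "dosewindow_log_error")
  }
  invisible(TRUE)
}

#' Summarize adherence from an event log
#'
#' Each slot's outcome is its final recorded status; a slot with no terminal
#' event counts as missed. "On time" means a take inside the dosing window
#' (the engine's `RESOLVED_TAKEN`); the stricter ideal of taking within one
#' hour of the intended time is reported separately as `strict_on_time_rate`.
#' Counts partition the schedule, so permuting events while preserving
#' per-slot order leaves the summary unchanged. All rates are 0 on an empty
#' schedule.
#'
#' @param log A data frame in the [events_to_df()] layout (or a list of
#'   `dose_event`s).
#' @param slots The `dose_slots` frame the log was produced against.
#' @param strict Reject logs that violate engine safety (default). With
#'   `strict = FALSE` duplicates are counted into `duplicate_dose_count`
#'   instead of raising an error.
#' @return An `adherence_summary`: counts `n_slots`, `n_taken_on_time`,
#'   `n_taken_late`, `n_skipped`, `n_missed`, `duplicate_dose_count`, and
#'   rates `on_time_rate`, `any_take_rate`, `strict_on_time_rate`.
#' @export
summarize_adherence <- function(log, slots, strict = TRUE) {
  if (!is.data.frame(log)) log <- events_to_df(log)
  stopifnot(inherits(slots, "dose_slots"))
  if (strict) {
    validate_event_log(log, slots)
    dup_count <- 0L
  } else {
    unknown <- setdiff(unique(log$slot_id), slots$slot_id)
    if (length(unknown)) {
      dw_abort("event log references unknown slot_id(s)", "dosewindow_log_error")
    }
    takes <- log$slot_id[log$action == "TAKE"]
    dup_count <- sum(table(takes) > 1L)
  }
  n <- nrow(slots)
  final <- vapply(slots$slot_id, function(id) {
    ev <- log[log$slot_id == id & log$resulting_status %in% TERMINAL_STATUSES, , drop = FALSE]
    if (!nrow(ev)) "RESOLVED_MISSED" else ev$resulting_status[nrow(ev)]
  }, character(1))
  n_on_time <- sum(final == "RESOLVED_TAKEN")
  n_late <- sum(final == "RESOLVED_TAKEN_LATE")
  n_skipped <- sum(final == "RESOLVED_SKIPPED")
  n_missed <- sum(final == "RESOLVED_MISSED")
  rate <- function(num) if (n == 0L) 0 else num / n
  strict_hits <- sum(vapply(seq_len(n), function(i) {
    id <- slots$slot_id[i]
    tk <- log[log$slot_id == id & log$action == "TAKE", , drop = FALSE]
    nrow(tk) > 0L &&
      abs(as.numeric(tk$timestamp[1]) - as.numeric(slots$intended_time[i])) <= 3600
  }, logical(1)))
  structure(
    list(
      n_slots = n,
      n_taken_on_time = n_on_time,
      n_taken_late = n_late,
      n_skipped = n_skipped,
      n_missed = n_missed,
      duplicate_dose_count = dup_count,
      on_time_rate = rate(n_on_time),
      any_take_rate = rate(n_on_time + n_late),
      strict_on_time_rate = rate(strict_hits)
    ),
    class = "adherence_summary"
  )
}

#' @export
print.adherence_summary <- function(x, ...) {
  cat(sprintf("<adherence_summary> %d slot(s)\n", x$n_slots))
  cat(sprintf("  taken on time %d | taken late %d | skipped %d | missed %d\n",
              x$n_taken_on_time, x$n_taken_late, x$n_skipped, x$n_missed))
  cat(sprintf("  on-time rate %.3f | any-take rate %.3f | strict (within 1 h) %.3f\n",
              x$on_time_rate, x$any_take_rate, x$strict_on_time_rate))
  if (x$duplicate_dose_count > 0) {
    cat(sprintf("  !! duplicate doses detected: %d\n", x$duplicate_dose_count))
  }
  invisible(x)
}

#' Serialize an adherence summary to JSON
#' @param summary An `adherence_summary`.
#' @return A JSON string.
#' @export
summary_to_json <- function(summary) {
  stopifnot(inherits(summary, "adherence_summary"))
  as.character(jsonlite::toJSON(unclass(summary), auto_unbox = TRUE, digits = NA,
                                pretty = TRUE))
}
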