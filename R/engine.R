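# Decision engine: classifies the moment of app opening against a dose slot
# (Upcoming / Act Now / Overdue), drives the take/snooze/skip state machine,
# recommends skipping once the window has closed, and prevents duplicate
# dosing by forcing an explicit take-or-skip decision on the next dose after
# an overdue take. State is an append-only event log; the current status of
# every slot is a pure fold over that log.

DOSE_STATUSES <- c("UPCOMING", "ACT_NOW", "OVERDUE",
                   "RESOLVED_TAKEN", "RESOLVED_TAKEN_LATE",
                   "RESOLVED_SKIPPED", "RESOLVED_MISSED")
TERMINAL_STATUSES <- c("RESOLVED_TAKEN", "RESOLVED_TAKEN_LATE",
                       "RESOLVED_SKIPPED", "RESOLVED_MISSED")
USER_ACTIONS <- c("TAKE", "SNOOZE", "SKIP", "TAKE_NEXT", "SKIP_NEXT")
MAX_CONSECUTIVE_SNOOZES <- 4L

#' Classify an instant against a dose slot
#'
#' `UPCOMING` before the window opens (more than 1 h before the intended
#' time), `ACT_NOW` inside the half-open dosing window, `OVERDUE` at or after
#' window end. A pure, total function of `(now, slot)`: the same slot always
#' yields the same classification.
#'
#' @param now POSIXct time(s); vectorized.
#' @param slot A single slot (row of a `dose_slots` frame).
#' @return Character vector of `"UPCOMING"`, `"ACT_NOW"`, or `"OVERDUE"`.
#' @export
classify <- function(now, slot) {
  t <- as.numeric(now)
  ws <- as.numeric(slot$window_start[[1]])
  we <- as.numeric(slot$window_end[[1]])
  ifelse(t < ws, "UPCOMING", ifelse(t < we, "ACT_NOW", "OVERDUE"))
}

#' Actions available in a given status
#'
#' In the window the user may take, snooze, or skip; past the window the
#' recommendation is to skip (taking remains possible, with the duplicate-dose
#' guard); before the window no action is offered. After 4 consecutive
#' snoozes on a slot the engine stops re-reminding, so `SNOOZE` drops out of
#' the offered set while the slot stays actionable.
#'
#' @param status One of the non-terminal statuses.
#' @param snoozes_used Consecutive snoozes already recorded on the slot.
#' @return Character vector of actions, with attribute `recommended` naming
#'   the recommended action (or `NA`).
#' @export
available_actions <- function(status, snoozes_used = 0L) {
  if (status %in% TERMINAL_STATUSES) {
    dw_abort(sprintf("slot is already resolved (%s); no actions available", status),
             "dosewindow_resolved_error")
  }
  acts <- switch(status,
    UPCOMING = character(),
    ACT_NOW = if (snoozes_used >= MAX_CONSECUTIVE_SNOOZES) c("TAKE", "SKIP")
              else c("TAKE", "SNOOZE", "SKIP"),
    OVERDUE = c("SKIP", "TAKE"),
    dw_abort(sprintf("unknown status '%s'", status), "dosewindow_state_error")
  )
  attr(acts, "recommended") <- if (status == "OVERDUE") "SKIP" else NA_character_
  acts
}

#' Start an engine over a slot schedule
#'
#' @param slots A `dose_slots` frame from [generate_slots()].
#' @return A `dose_engine` holding the schedule, an empty append-only event
#'   log, and per-slot fold state (resolution, consecutive snoozes, pending
#'   reminder, pending next-dose decision).
#' @export
engine_start <- function(slots) {
  stopifnot(inherits(slots, "dose_slots"))
  n <- nrow(slots)
  structure(
    list(
      slots = slots,
      events = list(),
      resolved = stats::setNames(rep(NA_character_, n), slots$slot_id),
      snoozes = stats::setNames(rep(0L, n), slots$slot_id),
      reminder_at = stats::setNames(rep(NA_real_, n), slots$slot_id),
      pending = NULL
    ),
    class = "dose_engine"
  )
}

#' @export
print.dose_engine <- function(x, ...) {
  cat(sprintf("<dose_engine> %d slot(s), %d event(s), %d resolved%s\n",
              nrow(x$slots), length(x$events), sum(!is.na(x$resolved)),
              if (!is.null(x$pending)) ", pending next-dose decision" else ""))
  invisible(x)
}

#' Status of a slot at an instant, respecting resolutions
#'
#' Unlike the pure [classify()], this errors on a slot that has already
#' reached a terminal state when `strict = TRUE` (the contract for callers
#' that should never re-classify resolved slots) and otherwise returns the
#' terminal status.
#'
#' @param engine A `dose_engine`.
#' @param slot_id Slot identifier.
#' @param now POSIXct instant.
#' @param strict Error on resolved slots?
#' @return A status string.
#' @export
slot_status <- function(engine, slot_id, now, strict = FALSE) {
  key <- as.character(slot_id)
  res <- engine$resolved[[key]]
  if (!is.na(res)) {
    if (strict) {
      dw_abort(sprintf("already-resolved: slot %s is %s", slot_id, res),
               "dosewindow_resolved_error")
    }
    return(res)
  }
  classify(now, slot_at(engine$slots, slot_id))
}

new_event <- function(slot_id, timestamp, action, resulting_status,
                      overdue_take = FALSE, reminder_at = NULL) {
  structure(list(slot_id = slot_id, timestamp = timestamp, action = action,
                 resulting_status = resulting_status, overdue_take = overdue_take,
                 reminder_at = reminder_at), class = "dose_event")
}

#' @export
print.dose_event <- function(x, ...) {
  extra <- if (!is.null(x$reminder_at)) sprintf(" reminder %s", format(x$reminder_at))
           else if (isTRUE(x$overdue_take)) " (overdue take)" else ""
  cat(sprintf("<dose_event> slot %s %s @ %s -> %s%s\n", x$slot_id, x$action,
              format(x$timestamp), x$resulting_status, extra))
  invisible(x)
}

next_unresolved_after <- function(engine, slot_id) {
  ids <- engine$slots$slot_id
  later <- ids[ids > slot_id]
  later <- later[is.na(engine$resolved[as.character(later)])]
  if (length(later)) later[1] else NA_integer_
}

resolve_slot <- function(engine, slot_id, status) {
  engine$resolved[[as.character(slot_id)]] <- status
  engine$reminder_at[[as.character(slot_id)]] <- NA_real_
  engine
}

#' Apply a user action to a slot
#'
#' Implements the state machine: `TAKE` in the window resolves the slot taken;
#' `TAKE` past the window resolves it taken-late and (when a later unresolved
#' slot exists) emits a next-dose decision that must be answered with
#' `TAKE_NEXT` or `SKIP_NEXT` before that next slot can be taken — this is the
#' duplicate-dose guard. `SNOOZE` leaves the slot active and schedules a
#' reminder 15 min later; `SKIP` resolves the slot skipped. `SKIP_NEXT`
#' resolves the guarded slot skipped without a take; `TAKE_NEXT` releases it.
#'
#' @param engine A `dose_engine`.
#' @param slot_id Target slot.
#' @param action One of `TAKE`, `SNOOZE`, `SKIP`, `TAKE_NEXT`, `SKIP_NEXT`.
#' @param now POSIXct instant of the action.
#' @return A list with `engine` (new state), `event` (the recorded
#'   `dose_event`), and `decision` (a `next_dose_decision` or `NULL`).
#' @export
apply_action <- function(engine, slot_id, action, now) {
  stopifnot(inherits(engine, "dose_engine"))
  if (!action %in% USER_ACTIONS) {
    dw_abort(sprintf("unknown action '%s'", action), "dosewindow_action_error")
  }
  slot <- slot_at(engine$slots, slot_id)
  key <- as.character(slot_id)

  if (action %in% c("TAKE_NEXT", "SKIP_NEXT")) {
    if (is.null(engine$pending) || engine$pending$next_slot_id != slot_id) {
      dw_abort(sprintf("no pending next-dose decision for slot %s", slot_id),
               "dosewindow_action_error")
    }
    engine$pending <- NULL
    if (action == "SKIP_NEXT") {
      engine <- resolve_slot(engine, slot_id, "RESOLVED_SKIPPED")
      ev <- new_event(slot_id, now, "SKIP_NEXT", "RESOLVED_SKIPPED")
    } else {
      ev <- new_event(slot_id, now, "TAKE_NEXT", classify(now, slot))
    }
    engine$events <- c(engine$events, list(ev))
    return(list(engine = engine, event = ev, decision = NULL))
  }

  if (!is.na(engine$resolved[[key]])) {
    dw_abort(sprintf("already-resolved: slot %s is %s", slot_id, engine$resolved[[key]]),
             "dosewindow_resolved_error")
  }
  if (!is.null(engine$pending) && engine$pending$next_slot_id == slot_id &&
      action == "TAKE") {
    dw_abort(sprintf(
      "pending-next-dose-decision: slot %s is guarded after an overdue take on slot %s; answer TAKE_NEXT or SKIP_NEXT first",
      slot_id, engine$pending$triggering_slot_id),
      "dosewindow_pending_decision_error")
  }
  status <- classify(now, slot)
  acts <- available_actions(status, engine$snoozes[[key]])
  if (!action %in% acts) {
    dw_abort(sprintf("illegal action %s for status %s on slot %s", action, status, slot_id),
             "dosewindow_action_error")
  }

  decision <- NULL
  if (action == "TAKE") {
    if (status == "ACT_NOW") {
      engine <- resolve_slot(engine, slot_id, "RESOLVED_TAKEN")
      ev <- new_event(slot_id, now, "TAKE", "RESOLVED_TAKEN")
    } else { # OVERDUE: taking after window end always records an overdue take,
             # regardless of any snooze history
      engine <- resolve_slot(engine, slot_id, "RESOLVED_TAKEN_LATE")
      ev <- new_event(slot_id, now, "TAKE", "RESOLVED_TAKEN_LATE", overdue_take = TRUE)
      nxt <- next_unresolved_after(engine, slot_id)
      if (!is.na(nxt)) {
        decision <- structure(
          list(triggering_slot_id = slot_id, next_slot_id = nxt,
               prompt = c("TAKE_NEXT", "SKIP_NEXT")),
          class = "next_dose_decision")
        engine$pending <- decision
      } # no successor: the decision resolves trivially to a no-op
    }
  } else if (action == "SNOOZE") {
    engine$snoozes[[key]] <- engine$snoozes[[key]] + 1L
    reminder <- now + SNOOZE_MINUTES * 60
    engine$reminder_at[[key]] <- as.numeric(reminder)
    ev <- new_event(slot_id, now, "SNOOZE", status, reminder_at = reminder)
  } else { # SKIP
    engine <- resolve_slot(engine, slot_id, "RESOLVED_SKIPPED")
    ev <- new_event(slot_id, now, "SKIP", "RESOLVED_SKIPPED")
  }
  engine$events <- c(engine$events, list(ev))
  list(engine = engine, event = ev, decision = decision)
}

#' @export
print.next_dose_decision <- function(x, ...) {
  cat(sprintf("<next_dose_decision> overdue take on slot %s guards slot %s: answer TAKE_NEXT or SKIP_NEXT\n",
              x$triggering_slot_id, x$next_slot_id))
  invisible(x)
}

#' Expire slots left unresolved
#'
#' Any unresolved slot whose successor's window has opened is marked
#' `RESOLVED_MISSED` with a synthetic `EXPIRE` event, guaranteeing at most one
#' non-terminal slot per regimen at any instant. A final slot (no successor)
#' only expires when `close_final = TRUE` and its window has closed, so an
#' overdue take on the last dose of a regimen remains possible while a run is
#' live. A pending next-dose decision whose guarded slot expires is cleared
#' (it resolves trivially).
#'
#' @param engine A `dose_engine`.
#' @param now POSIXct instant.
#' @param close_final Also expire a windowless-successor final slot whose
#'   window has closed (use at end of run for liveness).
#' @return A list with `engine` and `events` (possibly empty list of synthetic
#'   `dose_event`s).
#' @export
expire <- function(engine, now, close_final = FALSE) {
  stopifnot(inherits(engine, "dose_engine"))
  slots <- engine$slots
  out <- list()
  t <- as.numeric(now)
  n <- nrow(slots)
  for (i in seq_len(n)) {
    key <- as.character(slots$slot_id[i])
    if (!is.na(engine$resolved[[key]])) next
    expired <- if (i < n) t >= as.numeric(slots$window_start[i + 1L])
               else close_final && t >= as.numeric(slots$window_end[i])
    if (expired) {
      engine <- resolve_slot(engine, slots$slot_id[i], "RESOLVED_MISSED")
      ev <- new_event(slots$slot_id[i], now, "EXPIRE", "RESOLVED_MISSED")
      engine$events <- c(engine$events, list(ev))
      out <- c(out, list(ev))
      if (!is.null(engine$pending) && engine$pending$next_slot_id == slots$slot_id[i]) {
        engine$pending <- NULL
      }
    }
  }
  list(engine = engine, events = out)
}
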