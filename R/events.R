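# Event log I/O. The engine's append-only log serializes to JSON Lines, one
# event per line with ISO-8601 timestamps, so logs are diffable, streamable,
# and auditable outside R.

EVENT_LOG_SCHEMA <- "dosewindow-events/1"

#' Convert an engine's event list to a data frame
#'
#' @param events A list of `dose_event`s (e.g. `engine$events`).
#' @param tz Timezone for the timestamp columns.
#' @return A data frame with one row per event: `slot_id`, `timestamp`,
#'   `action`, `resulting_status`, `overdue_take`, `reminder_at`.
#' @export
events_to_df <- function(events, tz = "UTC") {
  if (!length(events)) {
    return(data.frame(slot_id = integer(), timestamp = .POSIXct(numeric(), tz = tz),
                      action = character(), resulting_status = character(),
                      overdue_take = logical(),
                      reminder_at = .POSIXct(numeric(), tz = tz)))
  }
  data.frame(
    slot_id = vapply(events, function(e) as.integer(e$slot_id), integer(1)),
    timestamp = .POSIXct(vapply(events, function(e) as.numeric(e$timestamp), numeric(1)), tz = tz),
    action = vapply(events, `[[`, character(1), "action"),
    resulting_status = vapply(events, `[[`, character(1), "resulting_status"),
    overdue_take = vapply(events, function(e) isTRUE(e$overdue_take), logical(1)),
    reminder_at = .POSIXct(vapply(events, function(e) {
      if (is.null(e$reminder_at)) NA_real_ else as.numeric(e$reminder_at)
    }, numeric(1)), tz = tz)
  )
}

#' Write an event log as JSON Lines
#'
#' @param events A list of `dose_event`s or a data frame from [events_to_df()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  df <- if (is.data.frame(events)) events else events_to_df(events)
  lines <- vapply(seq_len(nrow(df)), function(i) {
    rec <- list(
      schema = EVENT_LOG_SCHEMA,
      slot_id = df$slot_id[i],
      timestamp = fmt_iso8601(df$timestamp[i]),
      action = df$action[i],
      resulting_status = df$resulting_status[i],
      overdue_take = df$overdue_take[i],
      reminder_at = if (is.na(df$reminder_at[i])) NULL else fmt_iso8601(df$reminder_at[i])
    )
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null", digits = NA))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a JSON Lines event log
#'
#' @param path Path to a file written by [write_event_log()].
#' @param tz Timezone for the parsed timestamps.
#' @return A data frame in the [events_to_df()] layout.
#' @export
read_event_log <- function(path, tz = "UTC") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(events_to_df(list(), tz = tz))
  recs <- lapply(seq_along(lines), function(i) {
    tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
             error = function(e) dw_abort(sprintf("line %d: malformed event JSON", i),
                                          "dosewindow_parse_error"))
  })
  data.frame(
    slot_id = vapply(recs, function(r) as.integer(r$slot_id), integer(1)),
    timestamp = parse_iso8601(vapply(recs, `[[`, character(1), "timestamp"), tz = tz),
    action = vapply(recs, `[[`, character(1), "action"),
    resulting_status = vapply(recs, `[[`, character(1), "resulting_status"),
    overdue_take = vapply(recs, function(r) isTRUE(r$overdue_take), logical(1)),
    reminder_at = .POSIXct(vapply(recs, function(r) {
      if (is.null(r$reminder_at)) NA_real_ else as.numeric(parse_iso8601(r$reminder_at, tz = tz))
    }, numeric(1)), tz = tz)
  )
}
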