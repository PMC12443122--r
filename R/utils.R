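# Internal helpers: classed conditions, dash/number canonicalization, clock math.

`%||%` <- function(a, b) if (is.null(a)) b else a

# All package errors are classed so callers can branch on failure mode
# (e.g. not-found vs frequency-not-covered) without parsing messages.
dw_abort <- function(message, class, ..., call = sys.call(-1)) {
  cond <- structure(
    class = c(class, "dosewindow_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

# Table 1 uses en-dashes inside combination names and dose ranges; editors
# often substitute em-dashes or minus signs. Canonical form is ASCII hyphen.
canon_dashes <- function(x) {
  gsub("[‐‑‒–—−]", "-", x)
}

canon_name <- function(x) {
  tolower(trimws(canon_dashes(x)))
}

# "5–12.5–20" or "1,200" -> numeric vector; thousands separators stripped.
parse_dose_tuple <- function(x) {
  x <- canon_dashes(trimws(x))
  x <- gsub(",", "", x)          # thousands separators (doses only, never names)
  if (!nzchar(x)) return(numeric(0))
  parts <- strsplit(x, "-", fixed = TRUE)[[1]]
  out <- suppressWarnings(as.numeric(trimws(parts)))
  if (anyNA(out)) {
    dw_abort(sprintf("cannot parse dose tuple '%s'", x), "dosewindow_parse_error")
  }
  out
}

fmt_dose_tuple <- function(x) paste(format(x, trim = TRUE, scientific = FALSE), collapse = "-")

# "HH:MM" -> minutes since midnight
parse_hhmm <- function(x) {
  m <- regmatches(x, regexec("^([0-2]?[0-9]):([0-5][0-9])$", x))[[1]]
  if (length(m) != 3L || as.integer(m[2]) > 23L) {
    dw_abort(sprintf("invalid clock time '%s' (expected HH:MM)", x),
             "dosewindow_parse_error")
  }
  as.integer(m[2]) * 60L + as.integer(m[3])
}

fmt_hhmm <- function(mins) sprintf("%02d:%02d", mins %/% 60L, mins %% 60L)

# Wall-clock instant for a calendar date + clock time in a zone. During a
# spring-forward gap the requested wall-clock time does not exist (libc either
# normalizes it or returns NA); resolve to the earliest valid wall-clock
# instant at one-minute granularity (patients follow clocks). An ambiguous
# fall-back time takes whichever occurrence libc picks (the earlier one on
# glibc), which is also the earliest valid instant.
local_time <- function(date, hhmm_minutes, tz) {
  mk <- function(m) {
    suppressWarnings(as.POSIXct(sprintf("%s %s", format(date), fmt_hhmm(m %% 1440L)),
                                tz = tz))
  }
  round_trips <- function(t, m) {
    !is.na(t) && identical(format(t, "%H:%M", tz = tz), fmt_hhmm(m %% 1440L))
  }
  m <- hhmm_minutes
  t <- mk(m)
  tries <- 0L
  while (!round_trips(t, m) && tries < 180L) {
    m <- m + 1L
    t <- mk(m)
    tries <- tries + 1L
  }
  if (!round_trips(t, m)) {
    dw_abort(sprintf("cannot resolve local time %s %s in zone %s",
                     format(date), fmt_hhmm(hhmm_minutes), tz),
             "dosewindow_time_error")
  }
  t
}

# ISO-8601 with numeric offset; round-trips through the JSONL event log.
fmt_iso8601 <- function(t) format(t, "%Y-%m-%dT%H:%M:%S%z")

parse_iso8601 <- function(x, tz = "UTC") {
  t <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S%z", tz = tz)
  if (anyNA(t)) {
    dw_abort("cannot parse ISO-8601 timestamp(s)", "dosewindow_parse_error")
  }
  t
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == as.integer(x)
}
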