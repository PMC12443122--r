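# Shared fixtures and the independent classifier oracle.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# A tiny two-medication formulary built in code (no file I/O in unit tests).
tiny_formulary <- function() {
  new_formulary_for_tests(list(
    medication_entry("amlodipine", c("Norvasc", "Katerzia"), 2.5, 10, 1, 6,
                     dose_options = list(2.5, 5, 10)),
    medication_entry("examplepril", character(), 10, 40, 2, 3,
                     dose_options = list(10, 20, 40)),
    medication_entry("amlodipine-hct-olmesartan", "Tribenzor",
                     c(5, 12.5, 20), c(10, 25, 40), 1, 4)
  ))
}

# Formularies are normally built by load_formulary(); tests assemble them from
# entries through the same CSV path so every invariant is enforced.
new_formulary_for_tests <- function(entries) {
  lines <- vapply(entries, function(e) {
    paste(
      e$generic_name,
      if (length(e$brand_names)) sprintf("\"%s\"", paste(e$brand_names, collapse = ", ")) else "N",
      paste(e$min_dose_mg, collapse = "-"),
      paste(e$max_dose_mg, collapse = "-"),
      e$frequency_per_day,
      e$safe_window_hours,
      paste(vapply(e$dose_options, function(o) paste(o, collapse = "-"), character(1)),
            collapse = ";"),
      sep = ","
    )
  }, character(1))
  load_formulary(paste(c(paste(c("generic_name", "brand_names", "min_dose_mg",
                                 "max_dose_mg", "frequency_per_day",
                                 "safe_window_hours", "dose_options"),
                               collapse = ","), lines), collapse = "\n"),
                 format = "csv")
}

once_daily_regimen <- function(medication = "amlodipine", anchor = "08:00",
                               days = 7, start = "2026-01-05", tz = "UTC") {
  regimen(medication, 1, anchor, timezone = tz,
          start_date = start, end_date = as.Date(start) + days - 1)
}

bid_regimen <- function(days = 1, start = "2026-01-05") {
  regimen("examplepril", 2, c("08:00", "20:00"), timezone = "UTC",
          start_date = start, end_date = as.Date(start) + days - 1)
}

# Independent classifier oracle: works on minutes relative to the intended
# time and the safe window alone; never touches slot window_start/window_end.
oracle_status <- function(time, intended_time, safe_window_hours) {
  delta_min <- (as.numeric(time) - as.numeric(intended_time)) / 60
  ifelse(delta_min < -60, "UPCOMING",
         ifelse(delta_min < 60 * safe_window_hours, "ACT_NOW", "OVERDUE"))
}

# Minute grid spanning `hours` hours starting at `from`.
minute_grid <- function(from, hours) {
  from + seq(0, hours * 3600 - 60, by = 60)
}
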