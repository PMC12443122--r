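# Formulary: the curated table of oral antihypertensives that parameterizes
# every downstream decision. One entry per medication x dosing frequency,
# carrying component dose bounds, selectable dose options, and the
# expert-curated safe window (hours after the intended time during which a
# missed dose may still be taken).

FORMULARY_CSV_COLUMNS <- c(
  "generic_name", "brand_names", "min_dose_mg", "max_dose_mg",
  "frequency_per_day", "safe_window_hours", "dose_options"
)

#' Construct a single formulary entry
#'
#' An entry describes one medication at one dosing frequency. Combination
#' products (two or three active components in one tablet) carry per-component
#' dose tuples; component arity is inferred from the dose tuples, and component
#' names from the hyphenated generic name when the split matches that arity.
#'
#' @param generic_name Generic name; lower-cased and dash-canonicalized.
#' @param brand_names Character vector of brand names; `"N"` or empty means none.
#' @param min_dose_mg,max_dose_mg Numeric per-component dose bounds in mg.
#' @param frequency_per_day Positive integer doses per day.
#' @param safe_window_hours Hours after the intended time during which the
#'   missed dose may still be taken; must be positive and end before the next
#'   intended dose (`safe_window_hours < 24 / frequency_per_day`).
#' @param dose_options Optional list of per-component dose tuples selectable at
#'   onboarding; defaults to the distinct min/max bounds.
#' @return A `medication_entry` object.
#' @export
medication_entry <- function(generic_name, brand_names = character(),
                             min_dose_mg, max_dose_mg,
                             frequency_per_day, safe_window_hours,
                             dose_options = NULL) {
  generic_name <- canon_name(generic_name)
  brand_names <- as.character(brand_names)
  brand_names <- trimws(brand_names[nzchar(trimws(brand_names))])
  brand_names <- brand_names[toupper(brand_names) != "N"]
  min_dose_mg <- as.numeric(min_dose_mg)
  max_dose_mg <- as.numeric(max_dose_mg)
  if (length(min_dose_mg) != length(max_dose_mg)) {
    dw_abort(sprintf("%s: min/max dose tuples differ in arity", generic_name),
             "dosewindow_invariant_error", rule = "components-arity")
  }
  n_comp <- length(min_dose_mg)
  if (n_comp < 1L || n_comp > 3L) {
    dw_abort(sprintf("%s: %d components (1-3 allowed)", generic_name, n_comp),
             "dosewindow_invariant_error", rule = "components-arity")
  }
  parts <- strsplit(generic_name, "-", fixed = TRUE)[[1]]
  components <- if (length(parts) == n_comp) parts else generic_name
  frequency_per_day <- as.integer(frequency_per_day)
  safe_window_hours <- as.numeric(safe_window_hours)
  if (is.null(dose_options) || length(dose_options) == 0L) {
    dose_options <- unique(list(min_dose_mg, max_dose_mg))
  }
  dose_options <- lapply(dose_options, as.numeric)
  structure(
    list(
      generic_name = generic_name,
      brand_names = brand_names,
      components = components,
      min_dose_mg = min_dose_mg,
      max_dose_mg = max_dose_mg,
      frequency_per_day = frequency_per_day,
      safe_window_hours = safe_window_hours,
      dose_options = dose_options
    ),
    class = "medication_entry"
  )
}

#' @export
print.medication_entry <- function(x, ...) {
  brands <- if (length(x$brand_names)) paste(x$brand_names, collapse = ", ") else "none"
  cat(sprintf("<medication_entry> %s (brands: %s)\n", x$generic_name, brands))
  cat(sprintf("  dose: %s to %s mg, %d/day, safe window %g h, %d option(s)\n",
              fmt_dose_tuple(x$min_dose_mg), fmt_dose_tuple(x$max_dose_mg),
              x$frequency_per_day, x$safe_window_hours, length(x$dose_options)))
  invisible(x)
}

entry_key <- function(entry) {
  sprintf("%s@%d", entry$generic_name, entry$frequency_per_day)
}

new_formulary <- function(entries, version = "unversioned") {
  keys <- vapply(entries, entry_key, character(1))
  ord <- order(vapply(entries, `[[`, character(1), "generic_name"),
               vapply(entries, `[[`, integer(1), "frequency_per_day"),
               method = "radix")
  structure(list(entries = entries[ord], version = version), class = "formulary")
}

#' @export
print.formulary <- function(x, ...) {
  n_combo <- sum(vapply(x$entries, function(e) length(e$components) > 1L, logical(1)))
  cat(sprintf("<formulary> %d entries (%d combination products), version '%s'\n",
              length(x$entries), n_combo, x$version))
  invisible(x)
}

#' @export
length.formulary <- function(x) length(x$entries)

#' Load a formulary from CSV or JSON
#'
#' The CSV dialect has the columns
#' `generic_name, brand_names, min_dose_mg, max_dose_mg, frequency_per_day,
#' safe_window_hours, dose_options`. Brand cells may hold several
#' comma-separated names; `N` means no brand. Combination dose cells like
#' `5-12.5-20` (en-dash, em-dash, or hyphen) split into per-component tuples;
#' thousands separators (`1,200`) are stripped. `dose_options` is a
#' semicolon-separated list of dose tuples and may be empty (bounds are then
#' used as the options). The JSON dialect is an array of entry objects,
#' optionally wrapped in `{"version": ..., "entries": [...]}`.
#'
#' @param source Path to a file, or a character scalar holding the raw text.
#' @param format `"csv"` or `"json"`; inferred from a file extension when possible.
#' @param validate Run [validate_formulary()] and fail on any violation (default).
#' @return A `formulary` object, entries sorted by (generic name, frequency).
#' @export
load_formulary <- function(source, format = c("auto", "csv", "json"), validate = TRUE) {
  format <- match.arg(format)
  is_path <- length(source) == 1L && !grepl("\n", source) && file.exists(source)
  if (format == "auto") {
    format <- if (is_path && grepl("\\.json$", source, ignore.case = TRUE)) "json"
              else if (is_path) "csv"
              else if (grepl("^\\s*[\\[{]", source)) "json"
              else "csv"
  }
  text <- if (is_path) paste(readLines(source, warn = FALSE), collapse = "\n") else source
  if (!nzchar(trimws(text))) {
    dw_abort("no entries: input is empty", "dosewindow_parse_error")
  }
  entries <- if (format == "csv") parse_formulary_csv(text) else parse_formulary_json(text)
  if (length(entries$entries) == 0L) {
    dw_abort("no entries: input contains no formulary rows", "dosewindow_parse_error")
  }
  f <- new_formulary(entries$entries, version = entries$version)
  if (validate) {
    rep <- validate_formulary(f)
    if (!rep$ok) {
      msgs <- sprintf("[%s] %s: %s", rep$errors$rule, rep$errors$key, rep$errors$message)
      dw_abort(paste0("formulary validation failed:\n  ",
                      paste(msgs, collapse = "\n  ")),
               "dosewindow_invariant_error", report = rep,
               rule = rep$errors$rule[1])
    }
  }
  f
}

parse_formulary_csv <- function(text) {
  df <- tryCatch(
    utils::read.csv(textConnection(text), stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE,
                    strip.white = TRUE),
    error = function(e) dw_abort(paste("malformed CSV:", conditionMessage(e)),
                                 "dosewindow_parse_error")
  )
  missing <- setdiff(setdiff(FORMULARY_CSV_COLUMNS, "dose_options"), names(df))
  if (length(missing)) {
    dw_abort(paste("missing required column(s):", paste(missing, collapse = ", ")),
             "dosewindow_parse_error")
  }
  entries <- vector("list", nrow(df))
  problems <- character()
  for (i in seq_len(nrow(df))) {
    entries[[i]] <- tryCatch({
      opts_cell <- if ("dose_options" %in% names(df)) df$dose_options[i] else ""
      opts <- parse_dose_options(opts_cell)
      medication_entry(
        generic_name = df$generic_name[i],
        brand_names = strsplit(df$brand_names[i], ",", fixed = TRUE)[[1]],
        min_dose_mg = parse_dose_tuple(df$min_dose_mg[i]),
        max_dose_mg = parse_dose_tuple(df$max_dose_mg[i]),
        frequency_per_day = parse_scalar_number(df$frequency_per_day[i], i, "frequency_per_day"),
        safe_window_hours = parse_scalar_number(df$safe_window_hours[i], i, "safe_window_hours"),
        dose_options = opts
      )
    }, error = function(e) {
      problems <<- c(problems, sprintf("row %d (%s): %s", i, df$generic_name[i],
                                       conditionMessage(e)))
      NULL
    })
  }
  if (length(problems)) {
    dw_abort(paste0("malformed formulary row(s):\n  ", paste(problems, collapse = "\n  ")),
             "dosewindow_parse_error")
  }
  list(entries = entries, version = "csv")
}

parse_scalar_number <- function(x, row, col) {
  v <- suppressWarnings(as.numeric(gsub(",", "", trimws(x))))
  if (length(v) != 1L || is.na(v)) {
    dw_abort(sprintf("row %d, column %s: cannot parse number '%s'", row, col, x),
             "dosewindow_parse_error")
  }
  v
}

parse_dose_options <- function(cell) {
  cell <- trimws(cell %||% "")
  if (is.na(cell) || !nzchar(cell)) return(NULL)
  lapply(strsplit(cell, ";", fixed = TRUE)[[1]], parse_dose_tuple)
}

parse_formulary_json <- function(text) {
  x <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                error = function(e) dw_abort(paste("malformed JSON:", conditionMessage(e)),
                                             "dosewindow_parse_error"))
  version <- "json"
  if (!is.null(names(x)) && "entries" %in% names(x)) {
    version <- as.character(x$version %||% "json")
    x <- x$entries
  }
  entries <- lapply(seq_along(x), function(i) {
    e <- x[[i]]
    tryCatch(
      medication_entry(
        generic_name = e$generic_name,
        brand_names = unlist(e$brand_names) %||% character(),
        min_dose_mg = unlist(e$min_dose_mg),
        max_dose_mg = unlist(e$max_dose_mg),
        frequency_per_day = e$frequency_per_day,
        safe_window_hours = e$safe_window_hours,
        dose_options = if (!is.null(e$dose_options)) lapply(e$dose_options, unlist)
      ),
      error = function(err) dw_abort(sprintf("entry %d: %s", i, conditionMessage(err)),
                                     "dosewindow_parse_error")
    )
  })
  list(entries = entries, version = version)
}

#' Serialize a formulary to CSV or JSON
#'
#' Canonical form: entries sorted by (generic name, frequency), hyphens in
#' combination names and dose tuples, brand names comma-joined, dose options
#' semicolon-joined. `load_formulary(write_formulary(f))` round-trips.
#'
#' @param formulary A `formulary`.
#' @param path Optional output path; when `NULL` the text is returned.
#' @param format `"csv"` or `"json"`.
#' @return The serialized text, invisibly when written to `path`.
#' @export
write_formulary <- function(formulary, path = NULL, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(formulary, "formulary"))
  if (format == "csv") {
    rows <- vapply(formulary$entries, function(e) {
      cells <- c(
        e$generic_name,
        if (length(e$brand_names)) paste(e$brand_names, collapse = ", ") else "N",
        fmt_dose_tuple(e$min_dose_mg),
        fmt_dose_tuple(e$max_dose_mg),
        as.character(e$frequency_per_day),
        format(e$safe_window_hours, trim = TRUE),
        paste(vapply(e$dose_options, fmt_dose_tuple, character(1)), collapse = ";")
      )
      paste(vapply(cells, csv_quote, character(1)), collapse = ",")
    }, character(1))
    text <- paste(c(paste(FORMULARY_CSV_COLUMNS, collapse = ","), rows), collapse = "\n")
  } else {
    entries <- lapply(formulary$entries, function(e) {
      list(
        generic_name = e$generic_name,
        brand_names = as.list(e$brand_names),
        min_dose_mg = e$min_dose_mg,
        max_dose_mg = e$max_dose_mg,
        frequency_per_day = e$frequency_per_day,
        safe_window_hours = e$safe_window_hours,
        dose_options = e$dose_options
      )
    })
    text <- jsonlite::toJSON(list(schema = "dosewindow-formulary/1",
                                  version = formulary$version,
                                  entries = entries),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  as.character(text)
}

csv_quote <- function(x) {
  if (grepl('[",\n]', x)) paste0('"', gsub('"', '""', x), '"') else x
}

#' Look up a formulary entry by name and frequency
#'
#' Names resolve case-insensitively against generic names first, then brand
#' names ("Norvasc" resolves to amlodipine). A known name at an unlisted
#' frequency raises a distinct `dosewindow_frequency_error` so callers can
#' refuse to invent a safe window rather than interpolate one.
#'
#' @param formulary A validated `formulary`.
#' @param name Generic or brand name (case-insensitive).
#' @param frequency_per_day Doses per day.
#' @return The unique matching `medication_entry`.
#' @export
lookup <- function(formulary, name, frequency_per_day) {
  stopifnot(inherits(formulary, "formulary"))
  key <- canon_name(name)
  frequency_per_day <- as.integer(frequency_per_day)
  generics <- vapply(formulary$entries, `[[`, character(1), "generic_name")
  hits <- which(generics == key)
  if (!length(hits)) {
    brand_hit <- vapply(formulary$entries, function(e) {
      any(canon_name(e$brand_names) == key)
    }, logical(1))
    hits <- which(brand_hit)
  }
  if (!length(hits)) {
    near <- unique(c(
      generics[agrepl(key, generics, max.distance = 0.2)],
      unlist(lapply(formulary$entries, function(e) {
        b <- canon_name(e$brand_names)
        e$generic_name[any(agrepl(key, b, max.distance = 0.2))]
      }))
    ))
    hint <- if (length(near)) paste0("; did you mean: ", paste(utils::head(near, 5), collapse = ", "))
            else ""
    dw_abort(sprintf("medication '%s' not found in formulary%s", name, hint),
             "dosewindow_not_found_error", near_matches = near)
  }
  freqs <- vapply(formulary$entries[hits], `[[`, integer(1), "frequency_per_day")
  sel <- hits[freqs == frequency_per_day]
  if (!length(sel)) {
    dw_abort(sprintf(
      "'%s' is listed, but not at %d dose(s)/day (covered: %s); safe windows are curated per frequency and are never interpolated",
      name, frequency_per_day, paste(sort(freqs), collapse = ", ")),
      "dosewindow_frequency_error", covered_frequencies = sort(freqs))
  }
  formulary$entries[[sel[1]]]
}

#' Validate a formulary against its structural invariants
#'
#' Checks every entry-level rule (component arity, dose bounds, positive safe
#' window ending before the next intended dose, 1-11 in-bound dose options) and
#' the table-level rules (unique (generic, frequency) keys). All violations are
#' enumerated, not just the first; violations are data, not exceptions.
#'
#' @param formulary A `formulary`.
#' @return A `validation_report` with `errors`, `warnings` (data frames with
#'   columns `key`, `rule`, `message`) and `ok` (`TRUE` iff no errors).
#' @export
validate_formulary <- function(formulary) {
  stopifnot(inherits(formulary, "formulary"))
  err <- list()
  warn <- list()
  add <- function(store, key, rule, message) {
    c(store, list(data.frame(key = key, rule = rule, message = message)))
  }
  keys <- vapply(formulary$entries, entry_key, character(1))
  dup <- keys[duplicated(keys)]
  for (k in unique(dup)) {
    err <- add(err, k, "duplicate-key", "duplicate (generic_name, frequency) key")
  }
  for (e in formulary$entries) {
    k <- entry_key(e)
    nc <- length(e$components)
    if (nc < 1L || nc > 3L || length(e$min_dose_mg) != nc || length(e$max_dose_mg) != nc) {
      err <- add(err, k, "components-arity",
                 "component list and dose tuples must agree in arity (1-3)")
    }
    if (any(e$min_dose_mg > e$max_dose_mg)) {
      err <- add(err, k, "dose-bounds", "componentwise min dose exceeds max dose")
    }
    if (!is.finite(e$safe_window_hours) || e$safe_window_hours <= 0) {
      err <- add(err, k, "window-positive", "safe window must be positive")
    } else if (e$safe_window_hours >= 24 / e$frequency_per_day) {
      err <- add(err, k, "window-exceeds-interval",
                 sprintf("safe window %g h must end before the next dose (24/%d = %g h)",
                         e$safe_window_hours, e$frequency_per_day, 24 / e$frequency_per_day))
    }
    if (!is_count(e$frequency_per_day) || e$frequency_per_day < 1L) {
      err <- add(err, k, "frequency-positive", "frequency per day must be a positive integer")
    }
    nopt <- length(e$dose_options)
    if (nopt < 1L || nopt > 11L) {
      err <- add(err, k, "dose-options-count",
                 sprintf("%d dose options (1-11 allowed)", nopt))
    }
    for (opt in e$dose_options) {
      if (length(opt) != nc) {
        err <- add(err, k, "dose-option-arity", "dose option arity differs from components")
      } else if (any(opt < e$min_dose_mg - 1e-9) || any(opt > e$max_dose_mg + 1e-9)) {
        err <- add(err, k, "dose-option-bounds",
                   sprintf("dose option %s outside [%s, %s]", fmt_dose_tuple(opt),
                           fmt_dose_tuple(e$min_dose_mg), fmt_dose_tuple(e$max_dose_mg)))
      }
    }
    if (is.finite(e$safe_window_hours) && e$safe_window_hours > 0 &&
        !e$safe_window_hours %in% c(2, 3, 4, 6)) {
      warn <- add(warn, k, "unusual-window",
                  sprintf("safe window %g h is outside the curated set {2, 3, 4, 6}",
                          e$safe_window_hours))
    }
  }
  empty <- data.frame(key = character(), rule = character(), message = character())
  errors <- if (length(err)) do.call(rbind, err) else empty
  warnings <- if (length(warn)) do.call(rbind, warn) else empty
  structure(list(errors = errors, warnings = warnings, ok = nrow(errors) == 0L),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> ok=%s, %d error(s), %d warning(s)\n",
              x$ok, nrow(x$errors), nrow(x$warnings)))
  if (nrow(x$errors)) {
    cat(sprintf("  E [%s] %s: %s\n", x$errors$rule, x$errors$key, x$errors$message), sep = "")
  }
  if (nrow(x$warnings)) {
    cat(sprintf("  W [%s] %s: %s\n", x$warnings$rule, x$warnings$key, x$warnings$message), sep = "")
  }
  invisible(x)
}

#' Serialize a validation report to JSON
#' @param report A `validation_report`.
#' @return A JSON string.
#' @export
report_to_json <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  as.character(jsonlite::toJSON(
    list(ok = report$ok, errors = report$errors, warnings = report$warnings),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE))
}

#' Is a dose one of an entry's selectable options?
#'
#' @param entry A `medication_entry`.
#' @param dose Numeric per-component dose tuple in mg; arity must equal the
#'   number of components.
#' @return `TRUE` iff the tuple exactly matches one of `entry$dose_options`.
#' @export
validate_dose <- function(entry, dose) {
  stopifnot(inherits(entry, "medication_entry"))
  dose <- as.numeric(dose)
  if (length(dose) != length(entry$components)) {
    dw_abort(sprintf("dose tuple has arity %d, %s has %d component(s)",
                     length(dose), entry$generic_name, length(entry$components)),
             "dosewindow_arity_error")
  }
  any(vapply(entry$dose_options, function(opt) {
    length(opt) == length(dose) && all(abs(opt - dose) < 1e-9)
  }, logical(1)))
}

#' The shipped 21-row formulary excerpt
#'
#' Loads the packaged transcription of the printed formulary excerpt
#' (19 medications, 21 medication-frequency rows, including two- and
#' three-component combination products).
#'
#' @return A validated `formulary`.
#' @export
example_formulary <- function() {
  load_formulary(system.file("extdata", "formulary_table1.csv",
                             package = "dosewindow", mustWork = TRUE))
}
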