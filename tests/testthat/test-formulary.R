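test_that("CSV parsing handles printed-table conventions", {
  # en-dash combination tuples, quoted thousands separators, N for no brand
  csv <- paste(
    "generic_name,brand_names,min_dose_mg,max_dose_mg,frequency_per_day,safe_window_hours,dose_options",
    'acebutolol,N,200,"1,200",1,4,',
    "amlodipine–hct–olmesartan,Tribenzor,5–12.5–20,10–25–40,1,4,",
    sep = "\n"
  )
  f <- load_formulary(csv, format = "csv")
  aceb <- lookup(f, "acebutolol", 1)
  expect_identical(aceb$brand_names, character(0))
  expect_equal(aceb$min_dose_mg, 200)
  expect_equal(aceb$max_dose_mg, 1200)
  expect_equal(aceb$safe_window_hours, 4)

  combo <- lookup(f, "amlodipine-hct-olmesartan", 1)
  expect_length(combo$components, 3)
  expect_equal(combo$min_dose_mg, c(5, 12.5, 20))
  expect_equal(combo$max_dose_mg, c(10, 25, 40))
})

test_that("degenerate and malformed inputs are rejected with named context", {
  expect_error(load_formulary("", format = "csv"), "no entries",
               class = "dosewindow_parse_error")
  expect_error(load_formulary("generic_name,brand_names,min_dose_mg,max_dose_mg,frequency_per_day,safe_window_hours,dose_options\n",
                              format = "csv"),
               "no entries", class = "dosewindow_parse_error")
  bad <- "generic_name,brand_names,min_dose_mg,max_dose_mg,frequency_per_day,safe_window_hours,dose_options\nfoo,N,ten,20,1,4,"
  expect_error(load_formulary(bad, format = "csv"), "row 1",
               class = "dosewindow_parse_error")
  expect_error(load_formulary("generic_name,brand_names\nfoo,N", format = "csv"),
               "missing required column", class = "dosewindow_parse_error")
})

test_that("lookup resolves generics, brands, and refuses unknowns", {
  f <- example_formulary()
  expect_equal(lookup(f, "acebutolol", 1)$safe_window_hours, 4)
  expect_equal(lookup(f, "acebutolol", 2)$safe_window_hours, 2)
  norvasc <- lookup(f, "Norvasc", 1)
  expect_identical(norvasc$generic_name, "amlodipine")
  expect_equal(norvasc$safe_window_hours, 6)
  # excluded medication: never listed
  expect_error(lookup(f, "clonidine", 1), class = "dosewindow_not_found_error")
  # a known medication at an uncurated frequency must not be interpolated
  err <- expect_error(lookup(f, "amlodipine", 2), class = "dosewindow_frequency_error")
  expect_equal(err$covered_frequencies, 1L)
  # near-match hint on typos
  err2 <- expect_error(lookup(f, "amlodipin", 1), class = "dosewindow_not_found_error")
  expect_true("amlodipine" %in% err2$near_matches)
})

test_that("validate_formulary enumerates all violations with rule ids", {
  ok_rep <- validate_formulary(example_formulary())
  expect_true(ok_rep$ok)
  expect_equal(nrow(ok_rep$errors), 0)

  bad_csv <- paste(
    "generic_name,brand_names,min_dose_mg,max_dose_mg,frequency_per_day,safe_window_hours,dose_options",
    "awindow,N,10,20,2,13,",   # 13 >= 24/2
    "abounds,N,40,20,1,4,",    # min > max
    sep = "\n")
  f <- load_formulary(bad_csv, format = "csv", validate = FALSE)
  rep <- validate_formulary(f)
  expect_false(rep$ok)
  # (the min>max row also trips dose-option-bounds since options default to the bounds)
  expect_true(all(c("window-exceeds-interval", "dose-bounds") %in% rep$errors$rule))
  # violations are data: load_formulary with validation raises them as errors
  expect_error(load_formulary(bad_csv, format = "csv"),
               "window-exceeds-interval", class = "dosewindow_invariant_error")
  # report serializes
  expect_match(report_to_json(rep), "window-exceeds-interval")
})

test_that("duplicate (generic, frequency) keys are rejected", {
  dup <- paste(
    "generic_name,brand_names,min_dose_mg,max_dose_mg,frequency_per_day,safe_window_hours,dose_options",
    "foo,N,10,20,1,4,", "foo,N,10,20,1,6,", sep = "\n")
  f <- load_formulary(dup, format = "csv", validate = FALSE)
  expect_true("duplicate-key" %in% validate_formulary(f)$errors$rule)
})

test_that("validate_dose matches listed options exactly and checks arity", {
  f <- tiny_formulary()
  amlo <- lookup(f, "amlodipine", 1)
  expect_true(validate_dose(amlo, 5))
  expect_false(validate_dose(amlo, 7.5))
  combo <- lookup(f, "amlodipine-hct-olmesartan", 1)
  expect_error(validate_dose(combo, c(5, 12.5)), class = "dosewindow_arity_error")
  expect_true(validate_dose(combo, c(5, 12.5, 20)))
})

test_that("write/load round-trips in both CSV and JSON", {
  f <- example_formulary()
  for (fmt in c("csv", "json")) {
    f2 <- load_formulary(write_formulary(f, format = fmt), format = fmt)
    expect_equal(length(f2), length(f))
    keys <- function(x) vapply(x$entries, function(e)
      sprintf("%s@%d", e$generic_name, e$frequency_per_day), character(1))
    expect_identical(keys(f2), keys(f))
    for (i in seq_along(f$entries)) {
      e1 <- f$entries[[i]]; e2 <- f2$entries[[i]]
      expect_equal(e1$min_dose_mg, e2$min_dose_mg, info = fmt)
      expect_equal(e1$max_dose_mg, e2$max_dose_mg, info = fmt)
      expect_equal(e1$safe_window_hours, e2$safe_window_hours, info = fmt)
      expect_identical(e1$brand_names, e2$brand_names, info = fmt)
      expect_equal(e1$dose_options, e2$dose_options, info = fmt)
    }
    # serialization is canonical: a second round trip is bit-stable
    expect_identical(write_formulary(f2, format = fmt), write_formulary(f, format = fmt))
  }
})

test_that("shipped fixture satisfies every structural invariant", {
  f <- example_formulary()
  expect_equal(length(f), 21)
  expect_true(validate_formulary(f)$ok)
  for (e in f$entries) {
    expect_true(e$safe_window_hours %in% c(2, 3, 4, 6))
    expect_lt(e$safe_window_hours, 24 / e$frequency_per_day)
    expect_true(length(e$dose_options) >= 1 && length(e$dose_options) <= 11)
  }
  # entries sorted by (generic_name, frequency) on canonical serialization
  keys <- vapply(f$entries, function(e) e$generic_name, character(1))
  freqs <- vapply(f$entries, function(e) e$frequency_per_day, integer(1))
  expect_identical(order(keys, freqs, method = "radix"), seq_along(keys))
})
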