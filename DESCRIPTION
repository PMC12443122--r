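Package: dosewindow
Title: Safe-Window Decision Support for Missed Antihypertensive Doses
Version: 0.1.0
Authors@R:
    person("Dosewindow", "Maintainers", email = "maintainers@dosewindow.org",
           role = c("aut", "cre"))
Description: A rule-based decision-support engine for missed oral
    antihypertensive doses in older adults. Provides a validated formulary of
    medications with per-frequency safe windows, a routine-anchored dose
    scheduler, an Upcoming/Act-Now/Overdue classifier with take/snooze/skip
    actions and duplicate-dose prevention, an append-only event log with
    adherence summaries, and a seeded behaviour simulator plus a synthetic
    formulary generator so every rule is exercisable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
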