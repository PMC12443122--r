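# dosewindow

Rule-based decision support for **missed oral antihypertensive doses in older
adults**, for developers and researchers building medication-adherence tools
(digital therapeutics, reminder apps, adherence simulations).

When a dose intended for time $t_0$ is missed, the question is whether it is
still safe to take. Each medication–frequency pair carries an expert-curated
**safe window** $s$ (hours); the actionable **dosing window** is the half-open
interval

$$W = [\,t_0 - 1\,\text{h},\ t_0 + s\,).$$

Opening the app before $W$ is `UPCOMING` (no actions), inside $W$ is
`ACT_NOW` (take / snooze / skip; snooze re-reminds in 15 min), and at or past
$t_0 + s$ is `OVERDUE`: skipping is recommended, and taking anyway arms a
mandatory take-or-skip decision on the next scheduled dose so a double dose
can never happen silently.

The package provides:

* **formulary** — load/validate/query the safe-window table
  (`load_formulary`, `lookup`, `validate_formulary`, `validate_dose`); a
  21-row transcription of the published excerpt ships in
  `inst/extdata/formulary_table1.csv`;
* **schedule** — routine-anchored slot generation with DST-aware wall-clock
  anchors (`regimen`, `generate_slots`, `window_for`);
* **engine** — the classifier and take/snooze/skip state machine with
  duplicate-dose prevention, as a pure fold over an append-only event log
  (`classify`, `available_actions`, `apply_action`, `expire`);
* **adherence** — summaries from JSON-Lines event logs
  (`summarize_adherence`, `write_event_log`);
* **simulator** — seeded synthetic users and synthetic formularies so every
  rule is testable without patient data (`simulate_regimen`,
  `generate_synthetic_formulary`);
* **cli** — `exec/dosewindow` with `validate`, `lookup`, `classify`,
  `simulate`, `summarize` subcommands (JSON output; exit codes 0/1/2).

This is decision-support plumbing, not medical advice; safe windows are
consumed as data and never derived in-package.

## Worked example

```r
library(dosewindow)

f <- example_formulary()
lookup(f, "Norvasc", 1)        # brand resolves to its generic
#> <medication_entry> amlodipine (brands: Norvasc, Katerzia)
#>   dose: 2.5 to 10 mg, 1/day, safe window 6 h, 3 option(s)

r <- regimen("amlodipine", 1, c(breakfast = "08:00"), dose = 5,
             timezone = "America/New_York",
             start_date = "2026-01-05", end_date = "2026-01-11")
slots <- generate_slots(r, f)
slots[1, ]
#>   slot_id       intended_time        window_start          window_end
#> 1       1 2026-01-05 08:00:00 2026-01-05 07:00:00 2026-01-05 14:00:00
```

The 6-h safe window plus the 1-h lead give the daily window [07:00, 14:00).
At 13:30 the dose is still actionable; at 15:10 a take is recorded overdue and
the next dose is guarded:

```r
classify(as.POSIXct("2026-01-05 13:30", tz = "America/New_York"), slots[1, ])
#> [1] "ACT_NOW"

eng  <- engine_start(slots)
step <- apply_action(eng, 1L, "TAKE",
                     as.POSIXct("2026-01-05 15:10", tz = "America/New_York"))
step$event
#> <dose_event> slot 1 TAKE @ 2026-01-05 15:10:00 -> RESOLVED_TAKEN_LATE (overdue take)
step$decision
#> <next_dose_decision> overdue take on slot 1 guards slot 2: answer TAKE_NEXT or SKIP_NEXT
```

A seeded synthetic user over 30 days (default behaviour model: opens 90% of
the time, lognormal delay with 5-min median, mostly follows the overdue skip
recommendation):

```r
run <- simulate_regimen(r, f, behavior_model(seed = 7), n_days = 30)
run$summary
#> <adherence_summary> 30 slot(s)
#>   taken on time 25 | taken late 0 | skipped 2 | missed 3
#>   on-time rate 0.833 | any-take rate 0.833 | strict (within 1 h) 0.700
```

Of 30 scheduled doses this user took 25 inside the dosing window (on-time rate
0.833), followed the skip recommendation twice, never opened the app for the
remaining 3 (missed), and took 21 of 30 within an hour of 08:00 (the stricter
ideal, 0.700). `duplicate_dose_count` is 0 by construction — the engine cannot
emit a second take on a slot.

Command line:

```sh
exec/dosewindow lookup aliskiren 1                  # safe window 6 h, as JSON
exec/dosewindow classify amlodipine 1 08:00 15:00   # -> OVERDUE
exec/dosewindow simulate \
  --config inst/extdata/example_bid_config.json --seed 42 --out log.jsonl
```

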