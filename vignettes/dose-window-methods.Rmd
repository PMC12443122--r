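---
title: "Safe-window decision support for missed antihypertensive doses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Safe-window decision support: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosewindow)
```

## The problem and the model

Older adults on oral antihypertensives often miss a dose and then face a
question with no medication-specific guidance: is it still safe to take it?
`dosewindow` implements the rule engine for that decision. The central object
is the **safe window** $s$ (hours): an expert-curated, per-medication,
per-frequency duration after the intended dosing time during which the missed
dose may still be taken without overdose concern. Safe windows are consumed as
data — a formulary table — never derived from pharmacokinetics inside this
package.

For an intended dose at time $t_0$ the **dosing window** is

$$W = [\,t_0 - 1\,\mathrm{h},\; t_0 + s\,)$$

and the classifier is a total function of the current time $t$:
`UPCOMING` for $t < t_0 - 1\,\mathrm{h}$, `ACT_NOW` for $t \in W$, and
`OVERDUE` for $t \ge t_0 + s$. Inside the window the user chooses among
*take*, *snooze* (a new reminder 15 min later), and *skip*. Past the window the
engine *recommends* skipping — the choice stays with the user — and a take is
recorded as an overdue take, which arms a mandatory take-or-skip decision on
the next scheduled dose. That prompt is the duplicate-dose guard: the next
slot cannot be taken until the prompt is answered, and answering "skip next"
resolves it without a take.

## Formulary structure and invariants

One entry per (generic name, frequency per day): brand names, per-component
minimum/maximum doses in mg (combination products carry 2–3 components in one
tablet), selectable dose options, and the safe window. Structural invariants
enforced by `validate_formulary()`:

* component arity 1–3, identical across min/max and every dose option;
* componentwise `min <= max`, options within bounds, 1–11 options;
* `0 < safe_window_hours < 24 / frequency_per_day`, so a window always closes
  before the next intended dose;
* unique (generic, frequency) keys; canonical serialization sorts by them.

A known medication queried at an uncurated frequency raises a *distinct*
error class (`dosewindow_frequency_error`). This is deliberate: windows are
curated per frequency, and interpolating one would be unsafe.

The shipped fixture transcribes the 21 printed formulary rows (19
medications). The full supplementary table was not available as text, so
counts specific to it are out of reach; the synthetic generator
(`generate_synthetic_formulary()`) fills the testing gap with
invariant-satisfying formularies of arbitrary size. The printed table lists
only dose *bounds*; the fixture's dose options are plausible commercial
strengths within those bounds and are metadata only — no decision rule reads
them except regimen dose validation. One printed row (amiloride–HCT) pairs a
hyphenated name with scalar dose bounds; component arity is therefore
inferred from the dose tuples, not the name.

## Scheduling

A regimen ties each daily dose to a routine anchor (e.g. breakfast → 08:00).
`generate_slots()` expands it into one slot per anchor per day with windows as
above, and refuses regimens whose consecutive doses are not separated by more
than $s + 1$ h (`windows-overlap`): that spacing makes windows pairwise
disjoint, so every instant belongs to at most one window and the classifier is
unambiguous.

Numerical/boundary choices:

* **Half-open windows** `[start, end)`. Inclusivity is otherwise unstated; the
  half-open convention maps each instant to exactly one state, which the test
  suite checks by brute-force minute enumeration against an independent
  oracle.
* **One-minute granularity** throughout, matching reminder semantics
  (15-min snooze).
* **DST**: anchors are wall-clock times in the regimen's IANA zone. A
  spring-forward gap time resolves to the earliest valid wall-clock instant
  (02:30 in a 02:00→03:00 gap becomes 03:00); a fall-back duplicate takes its
  first occurrence. Schedules keep exactly `frequency_per_day` slots per
  calendar day through both transitions.
* Some minimal containers ship no tz database; the package detects degraded
  named-zone conversion at load and points `TZDIR` at the zoneinfo tree
  shipped alongside R, since silent UTC fallback would corrupt DST schedules.

## Engine state machine

Engine state is an append-only event log; every slot's status is a pure fold
over it, which makes the machine auditable and property-testable. Decisions
taken where the design was open:

* **`UPCOMING` permits no actions.** The label is only described as shown when
  the app is opened too early; allowing early takes would widen the effective
  window, so the conservative reading wins.
* **Snooze repetition** is unspecified beyond the 15-min interval. The engine
  allows at most 4 consecutive snoozes per slot, after which `SNOOZE` drops
  out of the offered action set while the slot stays actionable — bounded
  reminders without reminder-less snooze events.
* **A snoozed reminder that would fire after the window end** fires once; a
  take at that point is overdue (snoozing never extends the window), and an
  untouched slot is expired later. Intent here is unknowable from the source
  material; this choice keeps the safety property simple.
* **Expiry** is artifact plumbing: an unresolved slot is marked
  `RESOLVED_MISSED` once its successor's window opens, guaranteeing at most
  one non-terminal slot at any instant. A final slot (no successor) expires
  only when the driver closes the run, so an overdue take on the last dose of
  a regimen remains possible while it is live.
* **A next-dose prompt with no successor** (end of regimen) resolves to a
  no-op, and a prompt whose guarded slot expires is cleared.

The safety property — at most one take per slot, and after an overdue take the
next slot is either explicitly skipped or explicitly confirmed, never silently
taken — is enforced structurally and re-checked over 1,000 seeded simulator
runs in the acceptance suite.

## Adherence metrics

Two notions of "on time" both appear in the source material, so both are
reported: `on_time_rate` counts takes inside the dosing window (the operative
definition), and `strict_on_time_rate` counts takes within one hour of the
intended time (the stated ideal). Counts partition the schedule
(`taken on time + taken late + skipped + missed = slots`); a slot with no
terminal event counts as missed. Rates are 0 on an empty schedule (0/0 → 0).
Hand-written logs violating engine safety (two takes on one slot, unknown slot
ids) are rejected by `validate_event_log()`.

## What the simulator emulates — and what it does not

`simulate_regimen()` drives the engine through the public action API, so every
emitted event is legal at its timestamp. Per slot: the user opens the app with
probability `open_probability`; the open lands `delay` minutes from the
intended time; an early open waits for the window; an in-window open takes,
possibly after one snooze (`snooze_probability`); an overdue open takes with
`overdue_take_probability` (answering the next-dose prompt, skip/keep with
equal probability) and otherwise follows the skip recommendation.

Defaults are **illustrative, not empirical** — the source reports no
behavioural distributions: `open_probability = 0.9` (an engaged but imperfect
user), lognormal delay with median 5 min and `sdlog` chosen so roughly 10% of
opens land beyond a 4-h window, `overdue_take_probability = 0.25` (qualitative
literature has most patients skipping for fear of doubling up),
`snooze_probability = 0.2`. Randomness is one fixed-size uniform block per
slot keyed by `(seed, slot_id)`, so runs replay exactly, per-slot outcomes are
independent of iteration order, and — because the block is consumed
identically on every branch — enlarging the safe window can only convert
overdue opens into in-window takes, giving the monotonicity property the
acceptance suite checks.

The simulator does **not** model: multi-medication regimens and their
interactions, weekday/weekend routine shifts, behaviour change over time,
notification delivery failures, or any covariance between missing a dose and
the time of the next open. A green simulator-based test therefore establishes
the engine's logical properties (safety, determinism, monotonicity,
boundary placement), not any claim about real adherence behaviour.

## Known limitations

* The shipped formulary covers only the printed 21-row excerpt; the synthetic
  generator, not real data, provides breadth.
* Frequencies above twice daily never occur in the printed rows; the code
  supports them (the window invariant generalizes) but they are untested
  against curated data.
* Safe windows cannot be derived for new medications — by design, the
  formulary is data.
* Clock granularity is one minute; sub-minute event ordering is not defined.
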