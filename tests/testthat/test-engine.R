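amlo_slots <- function(days = 2) {
  generate_slots(once_daily_regimen(days = days), tiny_formulary())
}

test_that("classify follows the dosing-window rule with half-open boundaries", {
  slot <- amlo_slots(1)[1, ]  # intended 08:00, window [07:00, 14:00)
  expect_identical(classify(utc("2026-01-05 06:30"), slot), "UPCOMING")
  expect_identical(classify(utc("2026-01-05 07:00"), slot), "ACT_NOW")
  expect_identical(classify(utc("2026-01-05 13:59"), slot), "ACT_NOW")
  expect_identical(classify(utc("2026-01-05 14:00"), slot), "OVERDUE")
})

test_that("classify is total on the minute grid: one contiguous run per status", {
  # brute-force enumeration of a full day around the slot, against the oracle
  slot <- amlo_slots(1)[1, ]
  grid <- minute_grid(utc("2026-01-05 00:00"), 24)
  got <- classify(grid, slot)
  expect_identical(got, oracle_status(grid, slot$intended_time, 6))
  runs <- rle(got)
  expect_identical(runs$values, c("UPCOMING", "ACT_NOW", "OVERDUE"))
  expect_equal(runs$lengths[2], 60 * (1 + 6))
})

test_that("available actions per status, with the overdue skip recommendation", {
  expect_identical(as.vector(available_actions("ACT_NOW")), c("TAKE", "SNOOZE", "SKIP"))
  expect_true(is.na(attr(available_actions("ACT_NOW"), "recommended")))
  over <- available_actions("OVERDUE")
  expect_identical(as.vector(over), c("SKIP", "TAKE"))
  expect_identical(attr(over, "recommended"), "SKIP")
  expect_length(available_actions("UPCOMING"), 0)
  expect_error(available_actions("RESOLVED_TAKEN"), class = "dosewindow_resolved_error")
  # after 4 consecutive snoozes the engine stops offering snooze
  expect_identical(as.vector(available_actions("ACT_NOW", snoozes_used = 4L)),
                   c("TAKE", "SKIP"))
})

test_that("take in window resolves; snooze schedules a reminder in 15 min", {
  eng <- engine_start(amlo_slots(1))
  s1 <- apply_action(eng, 1L, "SNOOZE", utc("2026-01-05 08:10"))
  expect_equal(s1$event$reminder_at, utc("2026-01-05 08:25"))
  expect_identical(s1$event$resulting_status, "ACT_NOW")
  s2 <- apply_action(s1$engine, 1L, "TAKE", utc("2026-01-05 08:25"))
  expect_identical(s2$event$resulting_status, "RESOLVED_TAKEN")
  expect_false(s2$event$overdue_take)
  expect_null(s2$decision)
  expect_error(apply_action(s2$engine, 1L, "TAKE", utc("2026-01-05 08:30")),
               "already-resolved", class = "dosewindow_resolved_error")
})

test_that("overdue take emits a next-dose decision and guards the next slot", {
  eng <- engine_start(amlo_slots(2))
  s1 <- apply_action(eng, 1L, "TAKE", utc("2026-01-05 15:10"))
  expect_identical(s1$event$resulting_status, "RESOLVED_TAKEN_LATE")
  expect_true(s1$event$overdue_take)
  expect_equal(s1$decision$next_slot_id, 2L)
  # the guarded slot cannot be taken until the prompt is answered
  expect_error(apply_action(s1$engine, 2L, "TAKE", utc("2026-01-06 08:00")),
               "pending-next-dose-decision", class = "dosewindow_pending_decision_error")
  # SKIP_NEXT resolves it skipped without any user take
  s2 <- apply_action(s1$engine, 2L, "SKIP_NEXT", utc("2026-01-05 15:11"))
  expect_identical(s2$engine$resolved[["2"]], "RESOLVED_SKIPPED")
  # TAKE_NEXT leaves the slot active
  s3 <- apply_action(s1$engine, 2L, "TAKE_NEXT", utc("2026-01-05 15:11"))
  expect_true(is.na(s3$engine$resolved[["2"]]))
  s4 <- apply_action(s3$engine, 2L, "TAKE", utc("2026-01-06 08:00"))
  expect_identical(s4$event$resulting_status, "RESOLVED_TAKEN")
})

test_that("overdue take on the final slot resolves the decision trivially", {
  eng <- engine_start(amlo_slots(1))
  s1 <- apply_action(eng, 1L, "TAKE", utc("2026-01-05 16:00"))
  expect_null(s1$decision)
  expect_null(s1$engine$pending)
})

test_that("illegal actions are rejected for each status", {
  eng <- engine_start(amlo_slots(1))
  # no actions before the window opens
  expect_error(apply_action(eng, 1L, "TAKE", utc("2026-01-05 06:00")),
               class = "dosewindow_action_error")
  # snooze is not offered past the window
  expect_error(apply_action(eng, 1L, "SNOOZE", utc("2026-01-05 15:00")),
               class = "dosewindow_action_error")
  # next-dose answers need a pending prompt
  expect_error(apply_action(eng, 1L, "SKIP_NEXT", utc("2026-01-05 08:00")),
               class = "dosewindow_action_error")
})

test_that("snooze never extends the window; 5th snooze is not offered", {
  eng <- engine_start(amlo_slots(2))
  now <- utc("2026-01-05 13:00")
  for (i in 1:4) {
    st <- apply_action(eng, 1L, "SNOOZE", now)
    eng <- st$engine
    now <- st$event$reminder_at
  }
  expect_error(apply_action(eng, 1L, "SNOOZE", now), class = "dosewindow_action_error")
  # the snoozed chain has crossed 14:00: a take is now recorded overdue
  st <- apply_action(eng, 1L, "TAKE", now)
  expect_identical(st$event$resulting_status, "RESOLVED_TAKEN_LATE")
  expect_true(st$event$overdue_take)
})

test_that("expire marks stale slots missed and clears stale prompts", {
  slots <- amlo_slots(3)
  eng <- engine_start(slots)
  # slot 1 untouched; once slot 2's window opens it expires
  out <- expire(eng, utc("2026-01-06 07:00"))
  expect_length(out$events, 1)
  expect_identical(out$events[[1]]$resulting_status, "RESOLVED_MISSED")
  expect_identical(out$engine$resolved[["1"]], "RESOLVED_MISSED")
  # nothing left to expire at the same instant
  expect_length(expire(out$engine, utc("2026-01-06 07:00"))$events, 0)
  # final slot expires only at end of run
  fin <- expire(out$engine, utc("2026-01-08 12:00"))
  expect_false(identical(fin$engine$resolved[["3"]], "RESOLVED_MISSED"))
  fin2 <- expire(out$engine, utc("2026-01-08 12:00"), close_final = TRUE)
  expect_identical(fin2$engine$resolved[["3"]], "RESOLVED_MISSED")
  # guarded slot expiring clears the pending decision (trivial resolution)
  eng2 <- apply_action(engine_start(slots), 1L, "TAKE", utc("2026-01-05 15:00"))$engine
  expect_false(is.null(eng2$pending))
  eng3 <- expire(eng2, utc("2026-01-07 07:00"))$engine
  expect_null(eng3$pending)
})

test_that("a snoozed slot left alone expires when its successor opens", {
  # hand-enumerated trace: snooze at 13:55 -> reminder 14:10 lands past the
  # window end; the user never returns; the slot expires at the next window
  eng <- engine_start(amlo_slots(2))
  st <- apply_action(eng, 1L, "SNOOZE", utc("2026-01-05 13:55"))
  expect_equal(st$event$reminder_at, utc("2026-01-05 14:10"))
  out <- expire(st$engine, utc("2026-01-06 07:00"))
  expect_identical(out$engine$resolved[["1"]], "RESOLVED_MISSED")
  df <- events_to_df(out$engine$events)
  expect_identical(df$action, c("SNOOZE", "EXPIRE"))
})

test_that("slot_status folds resolutions over the event log", {
  eng <- engine_start(amlo_slots(2))
  expect_identical(slot_status(eng, 1L, utc("2026-01-05 09:00")), "ACT_NOW")
  eng <- apply_action(eng, 1L, "TAKE", utc("2026-01-05 09:00"))$engine
  expect_identical(slot_status(eng, 1L, utc("2026-01-05 09:00")), "RESOLVED_TAKEN")
  expect_error(slot_status(eng, 1L, utc("2026-01-05 09:00"), strict = TRUE),
               class = "dosewindow_resolved_error")
})
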