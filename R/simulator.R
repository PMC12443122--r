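# Behaviour simulator: a seeded synthetic user that opens the app around each
# intended dose, then acts through the engine exactly as a real user would
# (take / snooze / skip, overdue decisions, next-dose prompts). Every emitted
# action is legal at its timestamp, so simulator logs always pass engine
# validation. Also generates invariant-satisfying synthetic formularies for
# fuzzing.
#
# Randomness is one stream per slot, keyed by (seed, slot_id), and each slot
# consumes a fixed block of uniforms regardless of the branch taken. That
# makes per-slot outcomes reproducible independent of iteration order and
# makes any_take_rate monotone in the safe window (a larger window can only
# convert an overdue open into an in-window take).

#' Describe synthetic user behaviour
#'
#' @param open_probability Per-slot probability that the user opens the app at
#'   all. Default 0.9: a mostly-engaged user who still misses ~1 dose in 10.
#' @param delay_distribution How far from the intended time the open lands,
#'   in minutes: [delay_point()] or [delay_lognormal()]. The default is
#'   lognormal with median 5 min and sdlog such that about 10% of opens land
#'   beyond a 4-h safe window; purely illustrative, not empirical.
#' @param overdue_take_probability Probability that an overdue user takes
#'   anyway instead of following the skip recommendation. Default 0.25:
#'   patients predominantly skip for fear of doubling up.
#' @param snooze_probability Probability of snoozing once before taking when
#'   the open lands in the window. Default 0.2.
#' @param seed Integer seed; required for reproducibility.
#' @return A `behavior_model`.
#' @export
behavior_model <- function(open_probability = 0.9,
                           delay_distribution = delay_lognormal(),
                           overdue_take_probability = 0.25,
                           snooze_probability = 0.2,
                           seed = 1L) {
  probs <- c(open_probability, overdue_take_probability, snooze_probability)
  if (any(probs < 0) || any(probs > 1)) {
    dw_abort("probabilities must lie in [0, 1]", "dosewindow_model_error")
  }
  stopifnot(is.list(delay_distribution), !is.null(delay_distribution$family))
  structure(
    list(open_probability = open_probability,
         delay_distribution = delay_distribution,
         overdue_take_probability = overdue_take_probability,
         snooze_probability = snooze_probability,
         seed = as.integer(seed)),
    class = "behavior_model"
  )
}

#' Point-mass open delay
#' @param minutes Fixed delay (open time minus intended time) in minutes; must
#'   exceed -60 so the open never precedes the window start by construction.
#' @return A delay distribution spec.
#' @export
delay_point <- function(minutes) {
  if (minutes <= -60) {
    dw_abort("delay must exceed -60 min (support is (-60, Inf))", "dosewindow_model_error")
  }
  list(family = "point", minutes = minutes)
}

#' Lognormal open delay
#' @param median_minutes Median delay in minutes (support is positive: the
#'   user opens after the intended time).
#' @param sdlog Log-scale standard deviation. The default puts ~10% of opens
#'   past a 4-h (240-min) window when the median is 5 min.
#' @return A delay distribution spec.
#' @export
delay_lognormal <- function(median_minutes = 5,
                            sdlog = log(240 / 5) / stats::qnorm(0.9)) {
  if (median_minutes <= 0 || sdlog <= 0) {
    dw_abort("median_minutes and sdlog must be positive", "dosewindow_model_error")
  }
  list(family = "lognormal", meanlog = log(median_minutes), sdlog = sdlog)
}

delay_quantile <- function(dist, u) {
  switch(dist$family,
    point = dist$minutes,
    lognormal = stats::qlnorm(u, meanlog = dist$meanlog, sdlog = dist$sdlog),
    dw_abort(sprintf("unknown delay family '%s'", dist$family), "dosewindow_model_error")
  )
}

slot_uniforms <- function(seed, slot_id, n = 5L) {
  # keep the derived seed well inside 32-bit range (double arithmetic: the
  # product can exceed .Machine$integer.max before the final modulus)
  s <- (abs(as.numeric(seed)) %% 1000003) * 2039 + (as.numeric(slot_id) %% 2039)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(s %% 2147483647))
  stats::runif(n)
}

#' Simulate a user driving the engine over a regimen
#'
#' For each slot the synthetic user may open the app (with some delay from the
#' intended time), then acts through [apply_action()]: an open before the
#' window waits for the window to open; an in-window open takes (possibly
#' after one snooze, and a snooze whose reminder lands past the window end
#' falls through to the overdue logic); an overdue open takes with
#' `overdue_take_probability`, answering the next-dose prompt (skip or keep
#' the next dose with equal probability), and otherwise follows the skip
#' recommendation. Unopened or too-late slots expire to missed.
#'
#' @param regimen A `regimen` (its end date is ignored when `n_days` is given).
#' @param formulary A validated `formulary`.
#' @param model A `behavior_model`.
#' @param n_days Number of days to simulate; defaults to the regimen's span.
#' @return A list with `log` (event data frame), `summary`
#'   (an `adherence_summary`), `slots`, and the final `engine`.
#' @export
simulate_regimen <- function(regimen, formulary, model = behavior_model(),
                             n_days = NULL) {
  stopifnot(inherits(regimen, "regimen"), inherits(model, "behavior_model"))
  if (!is.null(n_days)) {
    if (!is_count(n_days)) dw_abort("n_days must be a non-negative count", "dosewindow_model_error")
    if (n_days == 0) {
      regimen$end_date <- regimen$start_date - 1L
    } else {
      regimen$end_date <- regimen$start_date + as.integer(n_days) - 1L
    }
  }
  slots <- generate_slots(regimen, formulary)
  engine <- engine_start(slots)
  minute <- function(t) .POSIXct(floor(as.numeric(t) / 60) * 60, tz = regimen$timezone)

  for (i in seq_len(nrow(slots))) {
    id <- slots$slot_id[i]
    u <- slot_uniforms(model$seed, id)
    if (u[1] >= model$open_probability) next  # never opens for this dose
    delay_min <- delay_quantile(model$delay_distribution, u[2])
    open_time <- minute(slots$intended_time[i] + delay_min * 60)
    # earlier slots whose successor window has opened expire before we act
    engine <- expire(engine, open_time)$engine
    if (!is.na(engine$resolved[[as.character(id)]])) next  # already skipped/expired
    act_time <- open_time
    if (classify(act_time, slot_at(slots, id)) == "UPCOMING") {
      act_time <- slots$window_start[i]  # opened early: waits for the window
    }
    status <- classify(act_time, slot_at(slots, id))
    if (status == "ACT_NOW" && u[3] < model$snooze_probability) {
      step <- apply_action(engine, id, "SNOOZE", act_time)
      engine <- step$engine
      act_time <- step$event$reminder_at
      status <- classify(act_time, slot_at(slots, id))
    }
    if (status == "ACT_NOW") {
      engine <- apply_action(engine, id, "TAKE", act_time)$engine
    } else { # OVERDUE
      if (u[4] < model$overdue_take_probability) {
        step <- apply_action(engine, id, "TAKE", act_time)
        engine <- step$engine
        if (!is.null(step$decision)) {
          answer <- if (u[5] < 0.5) "SKIP_NEXT" else "TAKE_NEXT"
          engine <- apply_action(engine, step$decision$next_slot_id, answer, act_time)$engine
        }
      } else {
        engine <- apply_action(engine, id, "SKIP", act_time)$engine
      }
    }
  }
  end_time <- if (nrow(slots)) slots$window_end[nrow(slots)] + 60 else Sys.time()
  engine <- expire(engine, end_time, close_final = TRUE)$engine
  log <- events_to_df(engine$events, tz = regimen$timezone)
  list(log = log,
       summary = summarize_adherence(log, slots),
       slots = slots,
       engine = engine)
}

SYLLABLES <- c("al", "am", "az", "ben", "car", "dil", "en", "fos", "il", "lo",
               "met", "nif", "ol", "pril", "quin", "ram", "sar", "tan", "tol",
               "val", "zide", "dip", "ine", "olol")

synth_name <- function(n_syl) {
  paste(sample(SYLLABLES, n_syl, replace = TRUE), collapse = "")
}

#' Generate a synthetic formulary for fuzzing
#'
#' Entries satisfy every formulary invariant by construction: 1-3 components,
#' safe windows drawn from the curated set \{2, 3, 4, 6\} and always ending
#' before the next intended dose, 1-11 in-bound dose options, unique
#' (generic, frequency) keys. Deterministic given the seed.
#'
#' @param n_entries Number of entries (>= 1).
#' @param seed Integer seed.
#' @return A validated `formulary`.
#' @export
generate_synthetic_formulary <- function(n_entries, seed = 1L) {
  if (!is_count(n_entries) || n_entries < 1L) {
    dw_abort("n_entries must be a positive count", "dosewindow_model_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed) %% 2147483647L)
  entries <- vector("list", n_entries)
  seen <- character()
  # guarantee single, double and triple products all appear once there is room
  forced <- rep_len(c(1L, 2L, 3L), min(n_entries, 3L))
  for (i in seq_len(n_entries)) {
    repeat {
      n_comp <- if (i <= length(forced)) forced[i]
                else sample(1:3, 1L, prob = c(0.6, 0.3, 0.1))
      comps <- vapply(seq_len(n_comp), function(j) synth_name(sample(2:3, 1L)), character(1))
      name <- paste(comps, collapse = "-")
      freq <- sample(c(1L, 2L), 1L, prob = c(0.8, 0.2))
      if (!sprintf("%s@%d", name, freq) %in% seen) break
    }
    seen <- c(seen, sprintf("%s@%d", name, freq))
    window <- sample(c(2, 3, 4, 6), 1L)   # all < 24/freq for freq in {1, 2}
    min_d <- sample(c(2.5, 5, 10, 12.5, 25, 50), n_comp, replace = TRUE)
    max_d <- min_d * sample(c(2, 4, 8), n_comp, replace = TRUE)
    n_opt <- sample(1:11, 1L)
    opts <- unique(lapply(seq_len(n_opt), function(k) {
      frac <- (k - 1) / max(n_opt - 1, 1)
      round(min_d + frac * (max_d - min_d), 2)
    }))
    brands <- if (stats::runif(1) < 0.5) character()
              else vapply(seq_len(sample(1:2, 1L)), function(j) {
                n <- synth_name(2); paste0(toupper(substr(n, 1, 1)), substr(n, 2, nchar(n)))
              }, character(1))
    entries[[i]] <- medication_entry(
      generic_name = name, brand_names = brands,
      min_dose_mg = min_d, max_dose_mg = max_d,
      frequency_per_day = freq, safe_window_hours = window,
      dose_options = opts
    )
  }
  new_formulary(entries, version = sprintf("synthetic-seed-%d", as.integer(seed)))
}
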