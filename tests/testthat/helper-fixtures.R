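# Shared fixture builders. Everything is generated in code at test time.

# A session log with exactly `successes` SUCCESS rows (plus optional other
# outcomes), built directly rather than through the engine, for tests of
# the analysis layer.
stub_log <- function(successes, others = 0L, facility = "BF",
                     session_index = 1L, subject_id = "T01",
                     duration_min = 45, task_variant = "one_button",
                     other_outcome = "EARLY_RELEASE") {
  n <- successes + others
  cap <- as.integer(duration_min * 60000)
  outcome <- c(rep("SUCCESS", successes), rep(other_outcome, others))
  trials <- data.frame(
    cued_button = rep(if (task_variant == "one_button") 0L else 1L, n),
    pressed_button = rep(1L, n),
    t_down_ms = if (n) seq(0L, by = 4000L, length.out = n) else integer(0),
    duration_ms = rep(60L, n),
    outcome = outcome,
    reward = outcome == "SUCCESS",
    stringsAsFactors = FALSE
  )
  session_log(
    subject_id = subject_id, facility = facility,
    session_index = session_index, datetime = "2026-02-02T09:00:00Z",
    config = task_config(task_variant = task_variant, session_cap_ms = cap,
                         rng_seed = 1L),
    actual_duration_ms = cap, trials = trials
  )
}

# Random non-overlapping press script against a 4-button panel.
random_script <- function(n = 40L, max_gap = 6000L, max_dur = 150L) {
  gaps <- sample.int(max_gap, n, replace = TRUE)
  durs <- sample.int(max_dur, n, replace = TRUE)
  t0 <- cumsum(gaps) + cumsum(c(0L, durs[-n]))
  data.frame(button = sample.int(4L, n, replace = TRUE),
             t_down_ms = t0, duration_ms = durs)
}

# Random valid session log produced by the engine (used for round-trip
# property tests).
random_session_log <- function(seed) {
  set.seed(seed)
  variant <- sample(c("one_button", "two_button", "four_button"), 1)
  script <- random_script(n = sample(1:40, 1))
  cap <- max(script$t_down_ms + script$duration_ms) + sample.int(60000, 1)
  cfg <- task_config(
    task_variant = variant, n_buttons = 4L,
    hold_time_ms = sample(c(30L, 50L, 80L), 1),
    timeout_ms = sample(c(0L, 1500L, 3000L), 1),
    timeout_prolong = sample(c("restart", "extend"), 1),
    session_cap_ms = cap,
    reward_units_per_success = sample(c(0.5, 1, 2), 1),
    rng_seed = sample.int(10000L, 1)
  )
  run_session(
    cfg, script,
    subject_id = sprintf("S%02d", sample.int(99, 1)),
    facility = sample(c("BF", "RF", "LAB"), 1),
    session_index = sample.int(30L, 1),
    datetime = sprintf("2026-0%d-1%dT0%d:30:00Z", sample.int(9, 1),
                       sample.int(9, 1) - 1, sample.int(9, 1)),
    annotation = sample(c("", "hand presses", "observer present, restless"), 1)
  )
}

# The default simulated cohort, built once per test run.
default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(cohort_spec())
    cache
  }
})

# Independent Mann-Whitney oracle: pairwise-counting U statistic and
# recursive subset enumeration (a different computational route from the
# package's rank-sum + combn implementation).
oracle_u_pairwise <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  min(u, length(x) * length(y) - u)
}

oracle_mw_exact <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  u_obs <- oracle_u_pairwise(x, y)
  count <- 0L; total <- 0L
  recurse <- function(start, chosen) {
    if (length(chosen) == nx) {
      xx <- pooled[chosen]; yy <- pooled[-chosen]
      total <<- total + 1L
      if (oracle_u_pairwise(xx, yy) <= u_obs + 1e-9) count <<- count + 1L
      return(invisible())
    }
    if (start > n) return(invisible())
    for (k in start:n) recurse(k + 1L, c(chosen, k))
  }
  recurse(1L, integer(0))
  list(u = u_obs, p = count / total)
}
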