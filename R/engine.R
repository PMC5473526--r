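#' @name engine
#' @title Deterministic engine for the cued button-press task
#'
#' @description
#' The engine is a seeded discrete-event state machine replaying the
#' automated training devices' trial loop. While a cue is lit, a press of
#' the cued button (any button on the one-button task) held for at least the
#' configured hold time is a `SUCCESS` and triggers a reward and a fresh
#' uniformly drawn cue. Pressing a wrong button (`WRONG_BUTTON`) or
#' releasing the correct one too early (`EARLY_RELEASE`) starts a time-out
#' with all cues off; presses attempted during the time-out are scored
#' `TIMEOUT_PRESS` and prolong it. After any error the \emph{same} cue
#' re-illuminates until it is correctly pressed, which discourages
#' stereotyped pressing of a single button.
#'
#' Time is integer milliseconds from session start; button ids are 1-based.
#' A success is registered at hold completion; release is not required.
#' All stochasticity (cue draws) comes from the engine's own stream seeded
#' by `rng_seed`, so identical configuration and press script give a
#' byte-identical session log.
NULL

OUTCOMES <- c("SUCCESS", "WRONG_BUTTON", "EARLY_RELEASE", "TIMEOUT_PRESS")

# Cue encoding used throughout the engine: a positive integer is the lit
# (and rewarded) button; 0L means "any button rewardable" (one-button task).
CUE_ANY <- 0L

#' Construct a press attempt
#'
#' @param button 1-based button id.
#' @param t_down_ms Press onset, ms since session start.
#' @param duration_ms Continuous hold duration, ms (> 0).
#' @return A `press_attempt` list.
#' @export
press_attempt <- function(button, t_down_ms, duration_ms) {
  p <- structure(
    list(button = as.integer(button), t_down_ms = as.integer(t_down_ms),
         duration_ms = as.integer(duration_ms)),
    class = "press_attempt"
  )
  if (is.na(p$button) || p$button < 1L) {
    stop("button id must be a positive integer", call. = FALSE)
  }
  if (is.na(p$t_down_ms) || p$t_down_ms < 0L) {
    stop("t_down_ms must be >= 0", call. = FALSE)
  }
  if (is.na(p$duration_ms) || p$duration_ms <= 0L) {
    stop("duration_ms must be > 0", call. = FALSE)
  }
  p
}

#' Initialise an engine session
#'
#' Seeds the engine stream from `config$rng_seed`, illuminates the first
#' cue at t = 0 and returns the initial state.
#'
#' @param config A [task_config()].
#' @return An `engine_state`: list with `clock_ms`, `cue` (button id, or 0
#'   for "any"), `timeout_until_ms` (`NA` when no time-out is pending),
#'   `trials` (list of scored trial records) and the private RNG state.
#' @examples
#' st <- init_session(task_config(rng_seed = 1))
#' st$cue
#' @export
init_session <- function(config) {
  validate_task_config(config)
  with_preserved_rng({
    set.seed(config$rng_seed)
    cue <- draw_cue(config)
    rng <- get_rng_state()
    structure(
      list(clock_ms = 0L, cue = cue, timeout_until_ms = NA_integer_,
           trials = list(), rng_state = rng),
      class = "engine_state"
    )
  })
}

# Uniform cue draw over the active buttons; consumes one draw from the
# current global RNG stream. One-button task: the cue is "any" (no draw).
draw_cue <- function(config) {
  n_active <- active_buttons(config$task_variant)
  if (config$task_variant == "one_button") CUE_ANY else sample.int(n_active, 1L)
}

#' Select the cue following a success (or at session start)
#'
#' One-button task: "any" (encoded `0L`). Two/four-button tasks: uniform
#' over the active buttons, immediate repeats allowed.
#'
#' @param state An `engine_state`.
#' @param config The session's [task_config()].
#' @return List with the drawn `cue` and the updated `state` (the engine
#'   RNG advances by one draw).
#' @export
select_next_cue <- function(state, config) {
  stopifnot(inherits(state, "engine_state"))
  with_preserved_rng({
    set_rng_state(state$rng_state)
    cue <- draw_cue(config)
    state$rng_state <- get_rng_state()
    list(cue = cue, state = state)
  })
}

# Pure scoring core shared by score_press(), run_session() and the subject
# simulator. No RNG; reports whether a fresh cue draw is needed.
score_core <- function(cue, timeout_until, press_button, t_down, duration,
                       config) {
  t_end <- t_down + duration
  if (!is.na(timeout_until) && t_down < timeout_until) {
    new_until <- if (config$timeout_prolong == "restart") {
      t_end + config$timeout_ms
    } else {
      timeout_until + config$timeout_ms
    }
    return(list(outcome = "TIMEOUT_PRESS", timeout_until = new_until,
                clock = t_end, new_cue_needed = FALSE))
  }
  match <- (cue == CUE_ANY) || (press_button == cue)
  if (match && duration >= config$hold_time_ms) {
    list(outcome = "SUCCESS", timeout_until = NA_integer_, clock = t_end,
         new_cue_needed = TRUE)
  } else if (!match) {
    list(outcome = "WRONG_BUTTON", timeout_until = t_end + config$timeout_ms,
         clock = t_end, new_cue_needed = FALSE)
  } else {
    list(outcome = "EARLY_RELEASE", timeout_until = t_end + config$timeout_ms,
         clock = t_end, new_cue_needed = FALSE)
  }
}

#' Score a single press attempt
#'
#' Applies the trial-loop rules (see [engine]) to one press and returns the
#' updated state together with the scored trial record.
#'
#' @param state An `engine_state` from [init_session()] or a previous call.
#' @param press A [press_attempt()]; must not start before the engine
#'   clock, and presses beyond the session cap raise a condition of class
#'   `autoprt_session_over`.
#' @param config The session's [task_config()].
#' @return List with elements `state` (updated) and `record` (named list:
#'   `cued_button`, `pressed_button`, `t_down_ms`, `duration_ms`,
#'   `outcome`, `reward`).
#' @examples
#' cfg <- task_config(rng_seed = 3)
#' st <- init_session(cfg)
#' res <- score_press(st, press_attempt(st$cue, 1000, 60), cfg)
#' res$record$outcome
#' @export
score_press <- function(state, press, config) {
  stopifnot(inherits(state, "engine_state"), inherits(press, "press_attempt"))
  if (press$t_down_ms < state$clock_ms) {
    stop("press starts before the engine clock (overlapping presses?)",
         call. = FALSE)
  }
  if (press$t_down_ms >= config$session_cap_ms) {
    stop(errorCondition(
      sprintf("press at %d ms is beyond the session cap (%d ms)",
              press$t_down_ms, config$session_cap_ms),
      class = "autoprt_session_over"
    ))
  }
  res <- score_core(state$cue, state$timeout_until_ms, press$button,
                    press$t_down_ms, press$duration_ms, config)
  record <- list(
    cued_button = state$cue,
    pressed_button = press$button,
    t_down_ms = press$t_down_ms,
    duration_ms = press$duration_ms,
    outcome = res$outcome,
    reward = identical(res$outcome, "SUCCESS")
  )
  state$clock_ms <- res$clock
  state$timeout_until_ms <- res$timeout_until
  if (res$new_cue_needed) {
    nxt <- select_next_cue(state, config)
    state <- nxt$state
    state$cue <- nxt$cue
  }
  state$trials[[length(state$trials) + 1L]] <- record
  list(state = state, record = record)
}

#' Replay a press script through a full session
#'
#' Scores every press in order until the session cap; presses at or beyond
#' the cap are dropped (the session is over). The result is a complete
#' [session_log()] carrying the configuration echo.
#'
#' @param config A [task_config()].
#' @param presses Data frame with columns `button`, `t_down_ms`,
#'   `duration_ms`, time-ordered and non-overlapping (each press must start
#'   at or after the previous press's release).
#' @param subject_id,facility,session_index,datetime,annotation Session
#'   header metadata (see [session_log()]).
#' @param actual_duration_ms Realised session duration; defaults to the cap.
#' @return A [session_log()].
#' @examples
#' cfg <- task_config(task_variant = "one_button", rng_seed = 1)
#' script <- data.frame(button = 1, t_down_ms = c(0, 500), duration_ms = 60)
#' log <- run_session(cfg, script)
#' table(log$trials$outcome)
#' @export
run_session <- function(config, presses,
                        subject_id = "anon", facility = "RF",
                        session_index = 1L,
                        datetime = "2026-01-05T09:00:00Z",
                        annotation = "",
                        actual_duration_ms = config$session_cap_ms) {
  validate_task_config(config)
  presses <- as.data.frame(presses)
  need <- c("button", "t_down_ms", "duration_ms")
  if (!all(need %in% names(presses))) {
    stop("press script must have columns button, t_down_ms, duration_ms",
         call. = FALSE)
  }
  n <- nrow(presses)
  btn <- as.integer(presses$button)
  t0 <- as.integer(presses$t_down_ms)
  dur <- as.integer(presses$duration_ms)
  if (n > 0L) {
    if (any(is.na(btn)) || any(is.na(t0)) || any(is.na(dur))) {
      stop("press script contains missing values", call. = FALSE)
    }
    if (any(dur <= 0L) || any(t0 < 0L) ||
        any(btn < 1L) || any(btn > config$n_buttons)) {
      stop("press script contains out-of-range values", call. = FALSE)
    }
    if (n > 1L && any(t0[-1L] < (t0 + dur)[-n])) {
      stop("press script is unordered or overlapping", call. = FALSE)
    }
  }

  with_preserved_rng({
    set.seed(config$rng_seed)
    cue <- draw_cue(config)
    timeout_until <- NA_integer_
    cued <- integer(n)
    outcome <- character(n)
    kept <- 0L
    for (i in seq_len(n)) {
      if (t0[i] >= config$session_cap_ms) break
      res <- score_core(cue, timeout_until, btn[i], t0[i], dur[i], config)
      kept <- i
      cued[i] <- cue
      outcome[i] <- res$outcome
      timeout_until <- res$timeout_until
      if (res$new_cue_needed) cue <- draw_cue(config)
    }
    idx <- seq_len(kept)
    trials <- data.frame(
      cued_button = cued[idx],
      pressed_button = btn[idx],
      t_down_ms = t0[idx],
      duration_ms = dur[idx],
      outcome = outcome[idx],
      reward = outcome[idx] == "SUCCESS",
      stringsAsFactors = FALSE
    )
    session_log(
      subject_id = subject_id, facility = facility,
      session_index = session_index, datetime = datetime,
      config = config, actual_duration_ms = actual_duration_ms,
      annotation = annotation, trials = trials
    )
  })
}

#' @export
print.engine_state <- function(x, ...) {
  cue <- if (identical(x$cue, CUE_ANY)) "any" else as.character(x$cue)
  to <- if (is.na(x$timeout_until_ms)) "none" else {
    sprintf("until %d ms", x$timeout_until_ms)
  }
  cat(sprintf("<engine_state> clock %d ms | cue %s | time-out %s | %d trial(s)\n",
              x$clock_ms, cue, to, length(x$trials)))
  invisible(x)
}
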