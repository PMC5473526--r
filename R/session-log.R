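#' A scored training session
#'
#' The canonical in-memory record of one training session: a header
#' (subject, facility, per-facility session index, start datetime, the full
#' task configuration echo, realised duration, free-text annotation) and a
#' body of scored trial records in press order.
#'
#' @param subject_id Subject identifier (non-empty string).
#' @param facility One of `"BF"` (breeding facility), `"RF"` (research
#'   facility) or `"LAB"` (laboratory).
#' @param session_index 1-based session index within the facility.
#' @param datetime Session start, ISO-8601 UTC (`"YYYY-MM-DDTHH:MM:SSZ"`).
#' @param config The [task_config()] in force for the session.
#' @param actual_duration_ms Realised duration; at most the session cap.
#' @param annotation Free text (e.g. trainer notes, press-mode remarks).
#' @param trials Data frame with columns `cued_button` (0 = any),
#'   `pressed_button`, `t_down_ms`, `duration_ms`, `outcome` (one of
#'   `SUCCESS`, `WRONG_BUTTON`, `EARLY_RELEASE`, `TIMEOUT_PRESS`), `reward`
#'   (logical). Rows must be time-ordered and lie within the duration.
#'
#' @return A validated object of class `session_log`.
#' @export
session_log <- function(subject_id, facility, session_index, datetime,
                        config, actual_duration_ms, annotation = "",
                        trials = empty_trials()) {
  log <- structure(
    list(
      subject_id = as.character(subject_id),
      facility = as.character(facility),
      session_index = as.integer(session_index),
      datetime = as.character(datetime),
      config = config,
      actual_duration_ms = as.integer(actual_duration_ms),
      annotation = as.character(annotation),
      trials = trials
    ),
    class = "session_log"
  )
  validate_session_log(log)
}

empty_trials <- function() {
  data.frame(
    cued_button = integer(0), pressed_button = integer(0),
    t_down_ms = integer(0), duration_ms = integer(0),
    outcome = character(0), reward = logical(0),
    stringsAsFactors = FALSE
  )
}

FACILITIES <- c("BF", "RF", "LAB")

#' Validate a session log against its invariants
#'
#' Checks header sanity (facility enum, 1-based index, duration within the
#' configured cap) and body invariants (known outcomes, non-decreasing
#' press times, presses within the session duration, reward iff success).
#'
#' @param log A [session_log()].
#' @return The log, invisibly-validated (errors on violation).
#' @export
validate_session_log <- function(log) {
  if (!inherits(log, "session_log")) stop("not a session_log", call. = FALSE)
  bad <- function(msg) stop("invalid session log: ", msg, call. = FALSE)
  if (is.na(log$subject_id) || !nzchar(log$subject_id)) bad("empty subject_id")
  if (!log$facility %in% FACILITIES) {
    bad(sprintf("facility must be one of %s", paste(FACILITIES, collapse = "/")))
  }
  if (is.na(log$session_index) || log$session_index < 1L) {
    bad("session_index must be >= 1")
  }
  parse_iso8601(log$datetime)
  validate_task_config(log$config)
  if (is.na(log$actual_duration_ms) || log$actual_duration_ms <= 0L) {
    bad("actual_duration_ms must be > 0")
  }
  if (log$actual_duration_ms > log$config$session_cap_ms) {
    bad("actual_duration_ms exceeds the session cap")
  }
  tr <- log$trials
  need <- c("cued_button", "pressed_button", "t_down_ms", "duration_ms",
            "outcome", "reward")
  if (!is.data.frame(tr) || !all(need %in% names(tr))) {
    bad("trials must be a data frame with the canonical columns")
  }
  if (nrow(tr)) {
    if (!all(tr$outcome %in% OUTCOMES)) bad("unknown outcome token")
    if (!identical(tr$reward, tr$outcome == "SUCCESS")) {
      bad("reward must be true exactly for SUCCESS rows")
    }
    if (any(tr$t_down_ms < 0L) || any(tr$duration_ms <= 0L)) {
      bad("negative press times or non-positive durations")
    }
    if (is.unsorted(tr$t_down_ms)) bad("press times must be non-decreasing")
    if (any(tr$t_down_ms >= log$actual_duration_ms)) {
      bad("press beyond the session duration")
    }
    if (any(tr$cued_button < 0L) ||
        any(tr$pressed_button < 1L) ||
        any(tr$pressed_button > log$config$n_buttons)) {
      bad("button id out of range")
    }
  }
  log
}

#' Count successful presses in a session log
#' @param log A [session_log()].
#' @return Integer count of `SUCCESS` trials.
#' @export
n_successes <- function(log) {
  sum(log$trials$outcome == "SUCCESS")
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log> %s | %s session %d | %s\n",
              x$subject_id, x$facility, x$session_index, x$datetime))
  cat(sprintf("  task: %s | %.1f min | %d press(es), %d success(es)\n",
              x$config$task_variant, x$actual_duration_ms / 60000,
              nrow(x$trials), n_successes(x)))
  invisible(x)
}

#' @export
summary.session_log <- function(object, ...) {
  m <- session_metrics(object)
  cat(sprintf("%s %s session %d (%s task, %.1f min)\n",
              object$subject_id, object$facility, object$session_index,
              object$config$task_variant, object$actual_duration_ms / 60000))
  print(table(factor(object$trials$outcome, levels = OUTCOMES)))
  cat(sprintf("correct presses/hour: %.1f | %% correct: %s\n",
              m$cp_per_hr,
              if (is.na(m$pct_correct)) "undefined" else sprintf("%.1f", m$pct_correct)))
  invisible(m)
}
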