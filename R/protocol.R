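#' Training-progression protocol configuration
#'
#' Encodes the staged training protocol: subjects work on an easy task
#' variant until a performance criterion fires, then move to the next stage
#' of their facility's stage order. At the breeding facility all training is
#' on the one-button task (a group-exposure week followed by two weeks of
#' individual sessions); at the research facility subjects progress from
#' the one-button to the four-button task once they reach the success
#' criterion; in the laboratory the first session uses the one-button task
#' after which subjects move to the two-button task, while the scheduled
#' session duration ramps from 10 to 36 minutes over the first 8 sessions.
#'
#' @param progression_threshold Successful presses needed to progress
#'   (default 100).
#' @param progression_basis `"per_session"` (successes in one session reach
#'   the threshold; the default) or `"per_hour"` (successes per realised
#'   hour reach it).
#' @param bf_group_phase_min_days Minimum working days of shared group
#'   access at the breeding facility (default 5, i.e. one week).
#' @param bf_individual_phase_min_days Minimum working days of individual
#'   sessions at the breeding facility (default 10, i.e. two weeks).
#' @param lab_ramp_start_min,lab_ramp_end_min,lab_ramp_sessions Laboratory
#'   session-duration ramp: linear from `lab_ramp_start_min` to
#'   `lab_ramp_end_min` minutes over `lab_ramp_sessions` sessions.
#' @param stage_order Named list of task-variant vectors per facility.
#' @param lab_progress_after_first If `TRUE` (default) the laboratory
#'   advances to its second stage after the first session regardless of the
#'   criterion, matching the training staff's practice; if `FALSE` the lab
#'   uses the same success criterion as the research facility.
#'
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(progression_threshold = 100L,
                            progression_basis = c("per_session", "per_hour"),
                            bf_group_phase_min_days = 5L,
                            bf_individual_phase_min_days = 10L,
                            lab_ramp_start_min = 10L,
                            lab_ramp_end_min = 36L,
                            lab_ramp_sessions = 8L,
                            stage_order = list(
                              BF = "one_button",
                              RF = c("one_button", "four_button"),
                              LAB = c("one_button", "two_button")
                            ),
                            lab_progress_after_first = TRUE) {
  progression_basis <- match.arg(progression_basis)
  cfg <- structure(
    list(
      progression_threshold = as.numeric(progression_threshold),
      progression_basis = progression_basis,
      bf_group_phase_min_days = as.integer(bf_group_phase_min_days),
      bf_individual_phase_min_days = as.integer(bf_individual_phase_min_days),
      lab_ramp_start_min = as.numeric(lab_ramp_start_min),
      lab_ramp_end_min = as.numeric(lab_ramp_end_min),
      lab_ramp_sessions = as.integer(lab_ramp_sessions),
      stage_order = stage_order,
      lab_progress_after_first = isTRUE(lab_progress_after_first)
    ),
    class = "protocol_config"
  )
  bad <- function(msg) stop("invalid protocol configuration: ", msg, call. = FALSE)
  if (cfg$progression_threshold <= 0) bad("progression_threshold must be > 0")
  if (cfg$lab_ramp_end_min < cfg$lab_ramp_start_min) {
    bad("lab_ramp_end_min must be >= lab_ramp_start_min")
  }
  if (cfg$lab_ramp_sessions < 2L) bad("lab_ramp_sessions must be >= 2")
  if (!all(FACILITIES %in% names(cfg$stage_order))) {
    bad("stage_order must name BF, RF and LAB")
  }
  cfg
}

protocol_config_fields <- function() {
  c("progression_threshold", "progression_basis", "bf_group_phase_min_days",
    "bf_individual_phase_min_days", "lab_ramp_start_min", "lab_ramp_end_min",
    "lab_ramp_sessions", "lab_progress_after_first")
}

protocol_config_from_list <- function(lst) {
  args <- lst[intersect(names(lst), protocol_config_fields())]
  do.call(protocol_config, args)
}

#' @export
print.protocol_config <- function(x, ...) {
  cat("<protocol_config>\n")
  cat(sprintf("  progression: >=%g successes (%s)\n",
              x$progression_threshold, x$progression_basis))
  cat(sprintf("  lab ramp: %g -> %g min over %d sessions\n",
              x$lab_ramp_start_min, x$lab_ramp_end_min, x$lab_ramp_sessions))
  invisible(x)
}

#' Has a subject met the stage-progression criterion?
#'
#' `TRUE` when any session of the current stage meets the threshold on the
#' configured basis: successes in the session (`per_session`) or successes
#' per realised hour (`per_hour`), both compared with `>=`.
#'
#' @param session_logs List of [session_log()]s from the current stage
#'   (empty history never progresses).
#' @param cfg A [protocol_config()].
#' @return Logical scalar.
#' @examples
#' should_progress(list(), protocol_config())  # FALSE
#' @export
should_progress <- function(session_logs, cfg = protocol_config()) {
  if (length(session_logs) == 0L) return(FALSE)
  any(vapply(session_logs, function(log) {
    s <- n_successes(log)
    if (cfg$progression_basis == "per_session") {
      s >= cfg$progression_threshold
    } else {
      hours <- log$actual_duration_ms / 3600000
      (s / hours) >= cfg$progression_threshold
    }
  }, logical(1)))
}

#' Scheduled laboratory session duration
#'
#' Linear ramp from `lab_ramp_start_min` to `lab_ramp_end_min` minutes over
#' the first `lab_ramp_sessions` laboratory sessions, rounded half-up to
#' whole minutes; constant at the maximum thereafter.
#'
#' @param k 1-based laboratory session index (vectorised).
#' @param cfg A [protocol_config()].
#' @return Session cap(s) in minutes.
#' @examples
#' lab_session_cap(1:9)  # 10 ... 36, 36
#' @export
lab_session_cap <- function(k, cfg = protocol_config()) {
  k <- as.integer(k)
  if (any(is.na(k)) || any(k < 1L)) {
    stop("session index k must be >= 1", call. = FALSE)
  }
  kk <- pmin(k, cfg$lab_ramp_sessions)
  frac <- (kk - 1) / (cfg$lab_ramp_sessions - 1)
  round_half_up(cfg$lab_ramp_start_min +
                  (cfg$lab_ramp_end_min - cfg$lab_ramp_start_min) * frac)
}

#' Current or next task stage for a subject
#'
#' Given a subject's session history at one facility, returns the task
#' variant the subject should train on next: the current stage, or the next
#' element of the facility's stage order once [should_progress()] holds on
#' the current stage's sessions. Stages are never skipped.
#'
#' A subject arriving at the research facility with no sessions yet resumes
#' the task settings last used at the breeding facility
#' (`bf_last_variant`), when given.
#'
#' @param history List of [session_log()]s at `facility`, in session order.
#' @param facility `"BF"`, `"RF"` or `"LAB"`.
#' @param cfg A [protocol_config()].
#' @param bf_last_variant Optional task variant last used at the breeding
#'   facility (used only for an empty RF history).
#' @return A task-variant string.
#' @export
next_task_stage <- function(history, facility, cfg = protocol_config(),
                            bf_last_variant = NULL) {
  if (!facility %in% FACILITIES) {
    stop("unknown facility: ", facility, call. = FALSE)
  }
  order <- cfg$stage_order[[facility]]
  if (length(history) == 0L) {
    if (facility == "RF" && !is.null(bf_last_variant)) {
      if (!bf_last_variant %in% order) {
        stop("breeding-facility variant not in the RF stage order",
             call. = FALSE)
      }
      return(bf_last_variant)
    }
    return(order[[1L]])
  }
  variants <- vapply(history, function(l) l$config$task_variant, character(1))
  if (!all(variants %in% order)) {
    stop("history contains a task variant outside the stage order",
         call. = FALSE)
  }
  current <- variants[[length(variants)]]
  pos <- match(current, order)
  if (pos == length(order)) return(current)
  if (facility == "LAB" && cfg$lab_progress_after_first) {
    # the lab moves on after its introductory session
    return(order[[pos + 1L]])
  }
  stage_logs <- history[variants == current]
  if (should_progress(stage_logs, cfg)) order[[pos + 1L]] else current
}
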