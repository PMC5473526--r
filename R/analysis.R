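#' Per-session performance measures
#'
#' The two session-level measures used throughout the behavioural analyses:
#' the rate of successful presses per hour of realised session time, and
#' the percentage of all recorded press attempts that were successful.
#' Because a success requires the button to be held for the full hold time,
#' the percentage can be below 100 even on the one-button task (early
#' releases count as attempts).
#'
#' @param log A [session_log()].
#' @param include_timeout_presses Should presses attempted during a
#'   time-out count in the attempt denominator? Default `TRUE` ("all
#'   presses"); set `FALSE` to restrict to cue-on attempts.
#' @return List of class `session_metrics`: `successes`, `attempts`,
#'   `cp_per_hr`, `pct_correct` (`NA` when there are no attempts — an
#'   undefined percentage, not zero).
#' @examples
#' cfg <- task_config(task_variant = "one_button", rng_seed = 1)
#' log <- run_session(cfg, data.frame(button = 1, t_down_ms = 0, duration_ms = 60))
#' session_metrics(log)
#' @export
session_metrics <- function(log, include_timeout_presses = TRUE) {
  validate_session_log(log)
  outcomes <- log$trials$outcome
  successes <- sum(outcomes == "SUCCESS")
  attempts <- if (include_timeout_presses) {
    length(outcomes)
  } else {
    sum(outcomes != "TIMEOUT_PRESS")
  }
  hours <- log$actual_duration_ms / 3600000
  structure(
    list(
      successes = successes,
      attempts = attempts,
      cp_per_hr = successes / hours,
      pct_correct = if (attempts == 0L) NA_real_ else 100 * successes / attempts
    ),
    class = "session_metrics"
  )
}

#' @export
print.session_metrics <- function(x, ...) {
  cat(sprintf("%d/%d successful | %.1f correct/h | %% correct: %s\n",
              x$successes, x$attempts, x$cp_per_hr,
              if (is.na(x$pct_correct)) "undefined"
              else sprintf("%.1f", x$pct_correct)))
  invisible(x)
}

#' Breeding-facility classification rule
#'
#' A subject counts as a "User" of the breeding-facility device when it
#' performed at least `user_min_successes` successful presses in at least
#' one session there; the default of 30 distinguishes genuine system use
#' from occasional accidental presses.
#'
#' @param user_min_successes Successes required in some single session.
#' @return Object of class `classification_rule`.
#' @export
classification_rule <- function(user_min_successes = 30L) {
  if (user_min_successes < 1L) {
    stop("user_min_successes must be >= 1", call. = FALSE)
  }
  structure(list(user_min_successes = as.integer(user_min_successes)),
            class = "classification_rule")
}

#' Classify a subject from its breeding-facility sessions
#'
#' `"UNEXPOSED"` when the subject has no breeding-facility sessions at all;
#' `"USER"` when any single session reaches the rule's success threshold;
#' `"NON_USER"` otherwise (exposed but never reached it).
#'
#' @param subject_logs List of the subject's BF [session_log()]s (possibly
#'   empty).
#' @param rule A [classification_rule()].
#' @return One of `"USER"`, `"NON_USER"`, `"UNEXPOSED"`.
#' @examples
#' classify_bf(list())  # "UNEXPOSED"
#' @export
classify_bf <- function(subject_logs, rule = classification_rule()) {
  if (length(subject_logs) == 0L) return("UNEXPOSED")
  for (log in subject_logs) {
    if (!identical(log$facility, "BF")) {
      stop("classify_bf expects breeding-facility logs only", call. = FALSE)
    }
  }
  best <- max(vapply(subject_logs, n_successes, integer(1)))
  if (best >= rule$user_min_successes) "USER" else "NON_USER"
}

#' Sessions to a performance criterion
#'
#' 1-based index of the first session in which the subject reached at least
#' `threshold` successful presses, regardless of task variant; `NA` when
#' the criterion was never reached.
#'
#' @param subject_logs List of [session_log()]s ordered by session index.
#' @param threshold Success-count criterion (default 100).
#' @return Integer session count, or `NA_integer_` (criterion not reached).
#' @export
sessions_to_criterion <- function(subject_logs, threshold = 100L) {
  s <- vapply(subject_logs, n_successes, integer(1))
  hit <- which(s >= threshold)
  if (length(hit)) hit[[1L]] else NA_integer_
}

#' Analysis-window specification
#'
#' An inclusive slice of a subject's sessions at one facility, anchored to
#' a protocol event: arrival at the facility (`"arrival"`), the first
#' session on a given task stage (`"stage_onset"`), or the start of
#' laboratory training (`"lab_onset"`, equivalent to arrival at the lab).
#'
#' Built-in windows (see [builtin_window()]): `rf_main` (research-facility
#' sessions 5-27 after arrival; the first four sessions are conventionally
#' discarded because individual attribution is unreliable there), `rf_4b`
#' (sessions 1-13 after four-button onset), `rf_early` (sessions 5-12) and
#' `lab_early` (laboratory sessions 1-8).
#'
#' @param name Window label.
#' @param facility `"BF"`, `"RF"` or `"LAB"`.
#' @param anchor `"arrival"`, `"stage_onset"` or `"lab_onset"`.
#' @param first_index,last_index 1-based inclusive indices relative to the
#'   anchor.
#' @param stage Task variant defining the anchor for `"stage_onset"`.
#' @return Object of class `window_spec`.
#' @export
window_spec <- function(name, facility, anchor = c("arrival", "stage_onset", "lab_onset"),
                        first_index, last_index, stage = NULL) {
  anchor <- match.arg(anchor)
  if (!facility %in% FACILITIES) stop("unknown facility", call. = FALSE)
  if (first_index > last_index) {
    stop("first_index must be <= last_index", call. = FALSE)
  }
  if (anchor == "stage_onset" && is.null(stage)) {
    stop("stage_onset windows need a stage", call. = FALSE)
  }
  structure(
    list(name = name, facility = facility, anchor = anchor,
         first_index = as.integer(first_index),
         last_index = as.integer(last_index), stage = stage),
    class = "window_spec"
  )
}

#' Built-in analysis windows
#' @param name One of `"rf_main"`, `"rf_4b"`, `"rf_early"`, `"lab_early"`.
#' @return A [window_spec()].
#' @export
builtin_window <- function(name = c("rf_main", "rf_4b", "rf_early", "lab_early")) {
  name <- match.arg(name)
  switch(name,
    rf_main = window_spec("rf_main", "RF", "arrival", 5L, 27L),
    rf_4b = window_spec("rf_4b", "RF", "stage_onset", 1L, 13L,
                        stage = "four_button"),
    rf_early = window_spec("rf_early", "RF", "arrival", 5L, 12L),
    lab_early = window_spec("lab_early", "LAB", "lab_onset", 1L, 8L)
  )
}

#' Select one subject's sessions falling in a window
#'
#' @param subject_logs List of one subject's [session_log()]s (any
#'   facilities; filtered internally).
#' @param spec A [window_spec()].
#' @return List of the logs in the window (inclusive slice relative to the
#'   anchor). Errors when the anchor event is absent from the history.
#' @export
select_window <- function(subject_logs, spec) {
  stopifnot(inherits(spec, "window_spec"))
  logs <- Filter(function(l) identical(l$facility, spec$facility), subject_logs)
  if (length(logs) == 0L) {
    stop(sprintf("no %s sessions: window anchor absent", spec$facility),
         call. = FALSE)
  }
  idx <- vapply(logs, function(l) l$session_index, integer(1))
  logs <- logs[order(idx)]
  idx <- sort(idx)
  anchor_idx <- if (spec$anchor %in% c("arrival", "lab_onset")) {
    1L
  } else {
    variants <- vapply(logs, function(l) l$config$task_variant, character(1))
    hit <- which(variants == spec$stage)
    if (!length(hit)) {
      stop(sprintf("subject never reached the %s stage: window anchor absent",
                   spec$stage), call. = FALSE)
    }
    idx[hit[[1L]]]
  }
  lo <- anchor_idx + spec$first_index - 1L
  hi <- anchor_idx + spec$last_index - 1L
  out <- logs[idx >= lo & idx <= hi]
  attr(out, "anchor_index") <- anchor_idx
  out
}

#' Group performance summary over an analysis window
#'
#' Implements the cohort-level summary used for group comparisons: for each
#' subject the across-session mean of the chosen measure inside the window
#' is computed first, then group means and standard errors are taken over
#' subjects, so each animal contributes one independent observation.
#' Per-session group means (the group learning curves) are also returned.
#'
#' @param cohort A [cohort_dataset()] whose subjects carry a `bf_class`
#'   column (see [classify_cohort()]).
#' @param window A [window_spec()] or a [builtin_window()] name.
#' @param measure `"cp_hr"` (successful presses per hour) or `"pct"`
#'   (percent correct).
#' @param include_timeout_presses Passed to [session_metrics()].
#' @return Object of class `prt_group_summary`: `groups` (data frame:
#'   group, n_subjects, mean, se — `se` is `NA` for single-subject
#'   groups), `subject_means`, `curves` (per relative session index), plus
#'   the window and measure. Empty groups are dropped with a warning.
#' @export
group_summary <- function(cohort, window = "rf_main",
                          measure = c("cp_hr", "pct"),
                          include_timeout_presses = TRUE) {
  measure <- match.arg(measure)
  stopifnot(inherits(cohort, "cohort_dataset"))
  if (is.character(window)) window <- builtin_window(window)
  if (anyNA(cohort$subjects$bf_class)) {
    stop("every subject must be classified; run classify_cohort() first",
         call. = FALSE)
  }

  measure_of <- function(log) {
    m <- session_metrics(log, include_timeout_presses)
    if (measure == "cp_hr") m$cp_per_hr else m$pct_correct
  }

  rows <- list()
  curve_rows <- list()
  for (i in seq_len(nrow(cohort$subjects))) {
    sid <- cohort$subjects$subject_id[[i]]
    logs <- subject_logs(cohort, sid)
    sel <- tryCatch(select_window(logs, window), error = function(e) NULL)
    if (is.null(sel) || length(sel) == 0L) next
    vals <- vapply(sel, measure_of, numeric(1))
    # session label relative to the window anchor (1-based at the anchor)
    rel <- vapply(sel, function(l) l$session_index, integer(1)) -
      attr(sel, "anchor_index") + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = sid, group = cohort$subjects$bf_class[[i]],
      n_sessions = length(vals), mean = mean(vals, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
    curve_rows[[length(curve_rows) + 1L]] <- data.frame(
      subject_id = sid, group = cohort$subjects$bf_class[[i]],
      session = rel, value = vals, stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) stop("no subject has sessions in this window", call. = FALSE)
  subject_means <- do.call(rbind, rows)
  per_session <- do.call(rbind, curve_rows)

  all_groups <- c("USER", "NON_USER", "UNEXPOSED")
  present <- intersect(all_groups, unique(subject_means$group))
  missing <- setdiff(intersect(all_groups, unique(cohort$subjects$bf_class)),
                     present)
  if (length(missing)) {
    warning("group(s) with no data in window omitted: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  groups <- do.call(rbind, lapply(present, function(g) {
    v <- subject_means$mean[subject_means$group == g]
    data.frame(
      group = g, n_subjects = length(v), mean = mean(v),
      se = if (length(v) < 2L) NA_real_ else stats::sd(v) / sqrt(length(v)),
      stringsAsFactors = FALSE
    )
  }))
  curves <- stats::aggregate(value ~ group + session, data = per_session, FUN = mean)
  names(curves)[names(curves) == "value"] <- "mean"
  curves <- curves[order(curves$group, curves$session), ]
  rownames(curves) <- NULL

  structure(
    list(window = window, measure = measure, groups = groups,
         subject_means = subject_means, curves = curves),
    class = "prt_group_summary"
  )
}

#' @export
print.prt_group_summary <- function(x, ...) {
  lab <- if (x$measure == "cp_hr") "correct presses/h" else "% correct"
  cat(sprintf("Group summary | window %s (%s sessions %d-%d) | %s\n",
              x$window$name, x$window$facility, x$window$first_index,
              x$window$last_index, lab))
  g <- x$groups
  for (i in seq_len(nrow(g))) {
    cat(sprintf("  %-9s n=%d  mean %.1f  SE %s\n", g$group[i], g$n_subjects[i],
                g$mean[i],
                if (is.na(g$se[i])) "n/a (single subject)"
                else sprintf("%.1f", g$se[i])))
  }
  invisible(x)
}

#' Plot group learning curves
#'
#' Per-session group means of the summarised measure across the analysis
#' window, one line per classification group (base graphics).
#'
#' @param x A `prt_group_summary`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.prt_group_summary <- function(x, ...) {
  wide <- stats::reshape(x$curves, idvar = "session", timevar = "group",
                         direction = "wide")
  wide <- wide[order(wide$session), ]
  groups <- sub("^mean\\.", "", names(wide)[-1L])
  cols <- c(USER = "forestgreen", NON_USER = "firebrick",
            UNEXPOSED = "darkorange")[groups]
  ylab <- if (x$measure == "cp_hr") "correct presses / h" else "% correct"
  graphics::matplot(wide$session, as.matrix(wide[, -1L, drop = FALSE]),
                    type = "b", pch = 16, lty = 1, col = cols,
                    xlab = sprintf("%s session (window %s)",
                                   x$window$facility, x$window$name),
                    ylab = ylab, ...)
  graphics::legend("topleft", legend = groups, col = cols, lty = 1, pch = 16,
                   bty = "n")
  invisible(x)
}
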