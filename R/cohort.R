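#' Specification of a simulated training cohort
#'
#' Describes a full study cohort: how many subjects of each learner
#' archetype, their facility itinerary (breeding-facility group and
#' individual phases, research-facility sessions, laboratory sessions),
#' the per-facility task settings and the master seed. The defaults mirror
#' the study conditions: 16 female rhesus macaques in small housing
#' groups, a week of shared group access plus two weeks of individual
#' sessions at the breeding facility (Unexposed subjects skip the breeding
#' facility entirely), at least 27 research-facility sessions and 8
#' laboratory sessions per subject, 50 ms hold time and a 3 s time-out.
#'
#' @param n_users,n_non_users,n_unexposed Subjects per archetype
#'   (defaults 8/5/3).
#' @param bf_group_sessions,bf_individual_sessions Breeding-facility
#'   session counts (group phase has reduced per-subject attribution).
#' @param rf_sessions,lab_sessions Research-facility and laboratory
#'   session counts.
#' @param bf_group_cap_min,bf_individual_cap_min,rf_cap_min Session caps in
#'   minutes (laboratory caps come from the protocol ramp).
#' @param hold_time_ms,timeout_ms Engine settings common to all facilities.
#' @param protocol A [protocol_config()].
#' @param master_seed Master seed; every session draws its own sub-seed
#'   from it.
#' @param start_date First breeding-facility training date (sessions run on
#'   working days).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_users = 8L, n_non_users = 5L, n_unexposed = 3L,
                        bf_group_sessions = 5L, bf_individual_sessions = 10L,
                        rf_sessions = 27L, lab_sessions = 8L,
                        bf_group_cap_min = 120, bf_individual_cap_min = 45,
                        rf_cap_min = 60,
                        hold_time_ms = 50L, timeout_ms = 3000L,
                        protocol = protocol_config(),
                        master_seed = 101L,
                        start_date = "2026-01-05") {
  spec <- structure(
    list(
      n_users = as.integer(n_users),
      n_non_users = as.integer(n_non_users),
      n_unexposed = as.integer(n_unexposed),
      bf_group_sessions = as.integer(bf_group_sessions),
      bf_individual_sessions = as.integer(bf_individual_sessions),
      rf_sessions = as.integer(rf_sessions),
      lab_sessions = as.integer(lab_sessions),
      bf_group_cap_min = as.numeric(bf_group_cap_min),
      bf_individual_cap_min = as.numeric(bf_individual_cap_min),
      rf_cap_min = as.numeric(rf_cap_min),
      hold_time_ms = as.integer(hold_time_ms),
      timeout_ms = as.integer(timeout_ms),
      protocol = protocol,
      master_seed = as.integer(master_seed),
      start_date = as.character(start_date)
    ),
    class = "cohort_spec"
  )
  bad <- function(msg) stop("infeasible cohort spec: ", msg, call. = FALSE)
  n <- spec$n_users + spec$n_non_users + spec$n_unexposed
  if (n < 1L) bad("no subjects")
  if (any(c(spec$n_users, spec$n_non_users, spec$n_unexposed) < 0L)) {
    bad("negative archetype count")
  }
  if (spec$rf_sessions < 1L || spec$lab_sessions < 1L) {
    bad("every subject needs research-facility and laboratory sessions")
  }
  if ((spec$n_users + spec$n_non_users) > 0L &&
      (spec$bf_group_sessions + spec$bf_individual_sessions) < 1L) {
    bad("exposed subjects need at least one breeding-facility session")
  }
  if (spec$lab_sessions < spec$protocol$lab_ramp_sessions &&
      spec$lab_sessions < 1L) {
    bad("lab itinerary shorter than one session")
  }
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d subjects (%d Users / %d Non-Users / %d Unexposed)\n",
              x$n_users + x$n_non_users + x$n_unexposed,
              x$n_users, x$n_non_users, x$n_unexposed))
  cat(sprintf("  itinerary: BF %d+%d | RF %d | Lab %d sessions | seed %d\n",
              x$bf_group_sessions, x$bf_individual_sessions,
              x$rf_sessions, x$lab_sessions, x$master_seed))
  invisible(x)
}

#' Bundle subjects and session logs into a cohort dataset
#'
#' @param subjects Data frame with at least `subject_id`, `housing_group`,
#'   `archetype` (or `"unknown"`), `bf_class` (may be `NA` until
#'   [classify_cohort()]); Table-1-shaped metadata columns (age, weight,
#'   rank) are carried through when present.
#' @param logs List of [session_log()]s.
#' @param provenance List (seed, spec checksum, ...) recorded verbatim.
#' @return Object of class `cohort_dataset`. Errors on orphan subject ids,
#'   duplicate (subject, facility, index) triples, or non-contiguous
#'   per-facility session indices.
#' @export
cohort_dataset <- function(subjects, logs, provenance = list()) {
  stopifnot(is.data.frame(subjects), "subject_id" %in% names(subjects))
  if (!"bf_class" %in% names(subjects)) subjects$bf_class <- NA_character_
  ds <- structure(
    list(subjects = subjects, logs = logs, provenance = provenance),
    class = "cohort_dataset"
  )
  ids <- vapply(logs, function(l) l$subject_id, character(1))
  orphans <- setdiff(unique(ids), subjects$subject_id)
  if (length(orphans)) {
    stop("session logs reference unknown subject id(s): ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  if (length(logs)) {
    fac <- vapply(logs, function(l) l$facility, character(1))
    idx <- vapply(logs, function(l) l$session_index, integer(1))
    key <- paste(ids, fac, idx)
    if (anyDuplicated(key)) {
      stop("duplicate session(s): ",
           paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
    }
    for (grp in split(idx, paste(ids, fac))) {
      if (!identical(sort(grp), seq_len(length(grp)))) {
        stop("per-facility session indices must be contiguous from 1 ",
             "(offending subject/facility: ",
             names(which(tapply(idx, paste(ids, fac), length) > 0))[1], ")",
             call. = FALSE)
      }
    }
  }
  ds
}

#' @export
print.cohort_dataset <- function(x, ...) {
  fac <- vapply(x$logs, function(l) l$facility, character(1))
  cat(sprintf("<cohort_dataset> %d subjects, %d session logs (%s)\n",
              nrow(x$subjects), length(x$logs),
              paste(sprintf("%s: %d", names(table(fac)), table(fac)),
                    collapse = ", ")))
  if (!anyNA(x$subjects$bf_class)) {
    cls <- table(x$subjects$bf_class)
    cat("  classified:", paste(sprintf("%s %d", names(cls), cls),
                               collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract one subject's logs from a cohort
#' @param cohort A [cohort_dataset()].
#' @param subject_id Subject identifier.
#' @param facility Optional facility filter.
#' @return List of [session_log()]s ordered by facility and session index.
#' @export
subject_logs <- function(cohort, subject_id, facility = NULL) {
  keep <- vapply(cohort$logs, function(l) {
    l$subject_id == subject_id &&
      (is.null(facility) || l$facility == facility)
  }, logical(1))
  logs <- cohort$logs[keep]
  ord <- order(
    match(vapply(logs, function(l) l$facility, character(1)), FACILITIES),
    vapply(logs, function(l) l$session_index, integer(1))
  )
  logs[ord]
}

#' Classify every cohort subject from breeding-facility performance
#' @param cohort A [cohort_dataset()].
#' @param rule A [classification_rule()].
#' @return The cohort with `subjects$bf_class` filled in.
#' @export
classify_cohort <- function(cohort, rule = classification_rule()) {
  cohort$subjects$bf_class <- vapply(cohort$subjects$subject_id, function(sid) {
    classify_bf(subject_logs(cohort, sid, facility = "BF"), rule)
  }, character(1))
  cohort
}

# --- simulation ------------------------------------------------------------

# Simulate one agent session against the engine. Consumes the global RNG
# (caller seeds it). Returns the trials data frame and the updated state.
simulate_agent_session <- function(params, astate, config,
                                   attribution = 1) {
  r <- astate$cumulative_rewards
  engaged <- stats::runif(1) < engage_prob_at(params, r) * attribution
  astate$engaged <- engaged
  if (!engaged) {
    return(list(trials = empty_trials(), state = astate))
  }
  cap <- config$session_cap_ms
  rate_per_ms <- engage_rate_at(params, r) * attribution / 60000
  cue <- draw_cue(config)
  timeout_until <- NA_integer_

  cap_n <- 4096L
  cued <- integer(cap_n); btn <- integer(cap_n)
  t0v <- integer(cap_n); durv <- integer(cap_n); outv <- character(cap_n)
  n <- 0L
  last_end <- 0L
  repeat {
    gap <- max(1L, as.integer(round_half_up(stats::rexp(1, rate_per_ms))))
    t_down <- last_end + gap
    if (t_down >= cap) break
    cue_view <- if (!is.na(timeout_until) && t_down < timeout_until) {
      NA_integer_
    } else {
      cue
    }
    g <- agent_press_geometry(params, astate, cue_view, config$n_buttons)
    dur <- max(1L, min(g$hold, cap - t_down))
    res <- score_core(cue, timeout_until, g$button, t_down, dur, config)
    n <- n + 1L
    if (n > cap_n) {
      cap_n <- cap_n * 2L
      length(cued) <- cap_n; length(btn) <- cap_n; length(t0v) <- cap_n
      length(durv) <- cap_n; length(outv) <- cap_n
    }
    cued[n] <- cue; btn[n] <- g$button; t0v[n] <- t_down; durv[n] <- dur
    outv[n] <- res$outcome
    timeout_until <- res$timeout_until
    if (res$outcome == "SUCCESS") {
      astate$cumulative_rewards <- astate$cumulative_rewards + 1L
      astate$p_correct <- p_correct_at(params, astate$cumulative_rewards)
      rate_per_ms <- engage_rate_at(params, astate$cumulative_rewards) *
        attribution / 60000
      cue <- draw_cue(config)
    }
    last_end <- t_down + dur
  }
  idx <- seq_len(n)
  trials <- data.frame(
    cued_button = cued[idx], pressed_button = btn[idx],
    t_down_ms = t0v[idx], duration_ms = durv[idx],
    outcome = outv[idx], reward = outv[idx] == "SUCCESS",
    stringsAsFactors = FALSE
  )
  list(trials = trials, state = astate)
}

#' Simulate a full training cohort
#'
#' Runs every subject of the spec through its complete itinerary —
#' breeding-facility group and individual phases (Unexposed subjects skip
#' these), research-facility sessions with per-subject stage progression,
#' and the laboratory with its session-duration ramp — against the task
#' engine, with each agent learning from its own rewards. Fully
#' reproducible from the master seed: each session draws a sub-seed
#' derived from (master seed, subject, facility, session index).
#'
#' @param spec A [cohort_spec()].
#' @return A classified [cohort_dataset()] (subjects carry both the
#'   generating `archetype` and the recovered `bf_class`).
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(cohort_spec(n_users = 1, n_non_users = 1,
#'                                       n_unexposed = 1, rf_sessions = 3,
#'                                       lab_sessions = 2))
#' cohort
#' }
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_users + spec$n_non_users + spec$n_unexposed
  archetypes <- rep(c("USER", "NON_USER", "UNEXPOSED"),
                    c(spec$n_users, spec$n_non_users, spec$n_unexposed))
  ids <- sprintf("S%02d", seq_len(n))

  subjects <- with_preserved_rng({
    set.seed(derive_seed(spec$master_seed, "subjects"))
    data.frame(
      subject_id = ids,
      housing_group = rep(seq_len(ceiling(n / 3)), each = 3L)[seq_len(n)],
      archetype = archetypes,
      age_months = sample(26:84, n, replace = TRUE),
      weight_kg = round(stats::runif(n, 3.3, 7.8), 2),
      rank = rep(c("Dom", "Mid", "Sub"), length.out = n),
      bf_class = NA_character_,
      stringsAsFactors = FALSE
    )
  })

  proto <- spec$protocol
  bf_days <- working_days(spec$start_date,
                          spec$bf_group_sessions + spec$bf_individual_sessions)
  rf_days <- working_days(as.Date(spec$start_date) + 35, spec$rf_sessions)
  lab_days <- working_days(as.Date(spec$start_date) + 95, spec$lab_sessions)
  day_iso <- function(d) paste0(format(d, "%Y-%m-%d"), "T09:00:00Z")

  logs <- vector("list", 0L)
  for (i in seq_len(n)) {
    sid <- ids[[i]]
    params <- make_agent(archetypes[[i]], spec$master_seed, sid)
    astate <- agent_state(params)

    run_one <- function(facility, k, variant, cap_min, attribution, date) {
      session_seed <- derive_seed(spec$master_seed, sid, facility, k)
      config <- task_config(
        task_variant = variant, n_buttons = 4L,
        hold_time_ms = spec$hold_time_ms, timeout_ms = spec$timeout_ms,
        session_cap_ms = as.integer(round(cap_min * 60000)),
        rng_seed = session_seed
      )
      with_preserved_rng({
        set.seed(session_seed)
        sim <- simulate_agent_session(params, astate, config, attribution)
        astate <<- sim$state
        session_log(
          subject_id = sid, facility = facility, session_index = k,
          datetime = day_iso(date), config = config,
          actual_duration_ms = config$session_cap_ms,
          annotation = if (attribution < 1) "group-exposure phase" else "",
          trials = sim$trials
        )
      })
    }

    if (archetypes[[i]] != "UNEXPOSED") {
      n_bf <- spec$bf_group_sessions + spec$bf_individual_sessions
      for (k in seq_len(n_bf)) {
        group_phase <- k <= spec$bf_group_sessions
        logs[[length(logs) + 1L]] <- run_one(
          "BF", k, "one_button",
          if (group_phase) spec$bf_group_cap_min else spec$bf_individual_cap_min,
          (if (group_phase) BF_GROUP_ATTRIBUTION else 1) *
            params$bf_engage_factor,
          bf_days[[k]]
        )
      }
    }

    rf_history <- list()
    for (k in seq_len(spec$rf_sessions)) {
      variant <- next_task_stage(rf_history, "RF", proto,
                                 bf_last_variant = "one_button")
      log <- run_one("RF", k, variant, spec$rf_cap_min, 1, rf_days[[k]])
      rf_history[[length(rf_history) + 1L]] <- log
      logs[[length(logs) + 1L]] <- log
    }

    lab_history <- list()
    for (k in seq_len(spec$lab_sessions)) {
      variant <- next_task_stage(lab_history, "LAB", proto)
      log <- run_one("LAB", k, variant, lab_session_cap(k, proto), 1,
                     lab_days[[k]])
      lab_history[[length(lab_history) + 1L]] <- log
      logs[[length(logs) + 1L]] <- log
    }
  }

  spec_chk <- fnv1a32(paste(utils::capture.output(utils::str(unclass(spec))),
                            collapse = "\n"))
  ds <- cohort_dataset(subjects, logs,
                       provenance = list(master_seed = spec$master_seed,
                                         spec_checksum = spec_chk))
  classify_cohort(ds)
}
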