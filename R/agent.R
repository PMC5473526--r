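#' Create a simulated subject's parameters
#'
#' Draws one subject's behavioural parameters around the archetype defaults
#' ([archetype_defaults()]): log-normal jitter on rates and time-constants,
#' clamped additive jitter on probabilities, so subjects within an
#' archetype are heterogeneous but ordered as the archetype intends. The
#' draw is deterministic in `(master_seed, subject_id)`.
#'
#' @param archetype `"USER"`, `"NON_USER"` or `"UNEXPOSED"`.
#' @param master_seed Cohort master seed.
#' @param subject_id Subject identifier string.
#' @return Object of class `agent_params`.
#' @examples
#' make_agent("USER", 7, "S01")$archetype
#' @export
make_agent <- function(archetype = c("USER", "NON_USER", "UNEXPOSED"),
                       master_seed, subject_id) {
  archetype <- match.arg(archetype)
  base <- archetype_defaults()[archetype, ]
  with_preserved_rng({
    set.seed(derive_seed(master_seed, "agent", subject_id))
    jit <- function(v) v * stats::rlnorm(1, 0, AGENT_JITTER_SDLOG)
    jit_p <- function(v) {
      min(0.995, max(0.005, v + stats::rnorm(1, 0, AGENT_JITTER_PROB)))
    }
    p0 <- base$p0_correct
    p_inf <- max(jit_p(base$p_inf_correct), p0)  # never below chance start
    structure(
      list(
        subject_id = subject_id,
        archetype = archetype,
        engage_prob0 = jit_p(base$engage_prob0),
        engage_prob = jit_p(base$engage_prob),
        engage_rate0_per_min = jit(base$engage_rate0_per_min),
        engage_rate_per_min = jit(base$engage_rate_per_min),
        tau_engage = jit(base$tau_engage),
        p0_correct = p0,
        p_inf_correct = p_inf,
        tau_trials = jit(base$tau_trials),
        hold_mean_ms = base$hold_mean_ms *
          stats::rlnorm(1, 0, AGENT_JITTER_HOLD),
        hold_sd_ms = base$hold_sd_ms,
        bf_engage_factor = base$bf_engage_factor,
        seed = derive_seed(master_seed, "agent", subject_id)
      ),
      class = "agent_params"
    )
  })
}

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf("<agent_params> %s (%s)\n", x$subject_id, x$archetype))
  cat(sprintf("  engage: p %.2f->%.2f, rate %.2f->%.2f /min (tau %.0f)\n",
              x$engage_prob0, x$engage_prob, x$engage_rate0_per_min,
              x$engage_rate_per_min, x$tau_engage))
  cat(sprintf("  cue-following: %.2f -> %.2f (tau %.0f) | hold %.0f+/-%.0f ms\n",
              x$p0_correct, x$p_inf_correct, x$tau_trials,
              x$hold_mean_ms, x$hold_sd_ms))
  invisible(x)
}

#' Initial learning state of an agent
#' @param params An [make_agent()] result.
#' @return Object of class `agent_state` with `cumulative_rewards`,
#'   `p_correct` and the session `engaged` flag.
#' @export
agent_state <- function(params) {
  structure(
    list(cumulative_rewards = 0L,
         p_correct = params$p0_correct,
         engaged = NA),
    class = "agent_state"
  )
}

# Exponential approach shared by all learning laws.
learn_curve <- function(v0, v_inf, tau, r) {
  v_inf - (v_inf - v0) * exp(-r / tau)
}

#' Cue-following probability after r rewards
#'
#' The agent's probability of aiming at the cued button follows
#' `p(r) = p_inf - (p_inf - p0) * exp(-r / tau)` in cumulative rewarded
#' trials r.
#'
#' @param params An `agent_params`.
#' @param rewards Cumulative reward count (vectorised).
#' @return Probability value(s).
#' @export
p_correct_at <- function(params, rewards) {
  learn_curve(params$p0_correct, params$p_inf_correct, params$tau_trials,
              rewards)
}

# Engagement quantities after r rewards (probability of engaging with the
# device this session; press rate per engaged minute).
engage_prob_at <- function(params, rewards) {
  learn_curve(params$engage_prob0, params$engage_prob, params$tau_engage,
              rewards)
}

engage_rate_at <- function(params, rewards) {
  learn_curve(params$engage_rate0_per_min, params$engage_rate_per_min,
              params$tau_engage, rewards)
}

#' Update an agent's learning state from a scored trial
#'
#' A `SUCCESS` increments the cumulative reward count and recomputes the
#' cue-following probability by the exponential law; all other outcomes
#' leave the learning state unchanged.
#'
#' @param state An [agent_state()].
#' @param record A trial record (named list with `outcome`) as produced by
#'   [score_press()].
#' @param params The agent's `agent_params`.
#' @return The updated `agent_state`.
#' @export
update_agent <- function(state, record, params) {
  if (identical(record$outcome, "SUCCESS")) {
    state$cumulative_rewards <- state$cumulative_rewards + 1L
    state$p_correct <- p_correct_at(params, state$cumulative_rewards)
  }
  state
}

# One button choice + hold draw. Consumes global RNG. cue_view: positive
# button id when a cue is lit, 0 for "any", NA while cues are off
# (time-out) -- the agent cannot follow a cue it cannot see and presses a
# uniformly random button.
agent_press_geometry <- function(params, state, cue_view, n_buttons) {
  button <- if (is.na(cue_view) || cue_view == CUE_ANY) {
    sample.int(n_buttons, 1L)
  } else if (stats::runif(1) < state$p_correct) {
    cue_view
  } else {
    others <- setdiff(seq_len(n_buttons), cue_view)
    others[sample.int(length(others), 1L)]
  }
  hold <- max(1L, as.integer(round_half_up(
    stats::rnorm(1, params$hold_mean_ms, params$hold_sd_ms))))
  list(button = button, hold = hold)
}

#' Let an agent act once against a cue
#'
#' Draws the agent's next press: an exponential inter-press gap at the
#' agent's engaged press rate, a button choice (the cued button with
#' probability `p_correct`, otherwise uniform among the other buttons; a
#' uniform button when no cue is visible), and a truncated-normal hold
#' duration (minimum 1 ms). Returns `NULL` (wait) when the agent is not
#' engaged this session or the press would start beyond `horizon_ms`.
#' Consumes the global RNG stream; seed it for reproducibility.
#'
#' @param params,state Agent parameters and state.
#' @param cue_view Lit cue: button id, `0` for "any", `NA` while cues are
#'   off.
#' @param clock_ms Time from which the inter-press gap is drawn.
#' @param n_buttons Number of physical buttons.
#' @param horizon_ms Session end; presses at or beyond it are not emitted.
#' @return A [press_attempt()] or `NULL`.
#' @export
agent_act <- function(params, state, cue_view, clock_ms, n_buttons = 4L,
                      horizon_ms = .Machine$integer.max) {
  if (!isTRUE(state$engaged)) return(NULL)
  rate_per_ms <- engage_rate_at(params, state$cumulative_rewards) / 60000
  gap <- max(1L, as.integer(round_half_up(stats::rexp(1, rate_per_ms))))
  t_down <- clock_ms + gap
  if (t_down >= horizon_ms) return(NULL)
  g <- agent_press_geometry(params, state, cue_view, n_buttons)
  press_attempt(g$button, t_down, min(g$hold, max(1L, horizon_ms - t_down)))
}
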