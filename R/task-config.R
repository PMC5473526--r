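#' Task configuration for the cued button-press engine
#'
#' Bundles every parameter of the automated positive-reinforcement-training
#' task: the task variant, the hold-time criterion, the post-error time-out
#' and its prolongation policy, the session duration cap and the engine seed.
#'
#' The three task variants follow the training devices' settings:
#' \describe{
#'   \item{`"one_button"`}{a press of \emph{any} button is rewardable (the
#'     cue is displayed but carries "any" semantics);}
#'   \item{`"two_button"`}{only the single cued button among buttons 1--2 is
#'     rewarded;}
#'   \item{`"four_button"`}{only the single cued button among buttons 1--4 is
#'     rewarded.}
#' }
#'
#' A press counts as successful when the cued (or, on the one-button task,
#' any) button is held continuously for at least `hold_time_ms`
#' milliseconds. Any error starts a time-out of `timeout_ms` during which
#' all cues are off and no reward is available; a press attempted during the
#' time-out prolongs it, either restarting the full period
#' (`timeout_prolong = "restart"`, the default) or appending one period
#' (`"extend"`).
#'
#' @param task_variant One of `"one_button"`, `"two_button"`,
#'   `"four_button"`.
#' @param n_buttons Number of physical buttons on the device; must be at
#'   least the number of active buttons of the variant.
#' @param hold_time_ms Minimum continuous press duration (ms) for a success.
#' @param timeout_ms Post-error time-out duration (ms); the device's value
#'   is adjustable, 3000 ms is the package default.
#' @param timeout_prolong `"restart"` or `"extend"` (see Details).
#' @param session_cap_ms Scheduled session duration (ms); presses at or
#'   beyond the cap are not scored.
#' @param reward_units_per_success Reward volume bookkeeping per success
#'   (arbitrary units; does not affect scoring).
#' @param refractory_ms Delay (ms) between a success and the illumination of
#'   the next cue. The physical device's behaviour here is undocumented, so
#'   the default is 0; a press landing inside the refractory window is
#'   scored against the already-selected next cue.
#' @param rng_seed Integer seed for the engine's cue-selection stream.
#'
#' @return An object of class `task_config` (a validated named list).
#' @examples
#' cfg <- task_config(task_variant = "four_button", rng_seed = 42)
#' cfg$hold_time_ms
#' @export
task_config <- function(task_variant = c("four_button", "one_button", "two_button"),
                        n_buttons = 4L,
                        hold_time_ms = 50L,
                        timeout_ms = 3000L,
                        timeout_prolong = c("restart", "extend"),
                        session_cap_ms = 1800000L,
                        reward_units_per_success = 1,
                        refractory_ms = 0L,
                        rng_seed = 1L) {
  task_variant <- match.arg(task_variant)
  timeout_prolong <- match.arg(timeout_prolong)
  cfg <- structure(
    list(
      task_variant = task_variant,
      n_buttons = as.integer(n_buttons),
      hold_time_ms = as.integer(hold_time_ms),
      timeout_ms = as.integer(timeout_ms),
      timeout_prolong = timeout_prolong,
      session_cap_ms = as.integer(session_cap_ms),
      reward_units_per_success = as.numeric(reward_units_per_success),
      refractory_ms = as.integer(refractory_ms),
      rng_seed = as.integer(rng_seed)
    ),
    class = "task_config"
  )
  validate_task_config(cfg)
}

#' Number of active (cue-eligible) buttons of a task variant
#' @param task_variant A variant string as in [task_config()].
#' @return Integer count of active buttons.
#' @export
active_buttons <- function(task_variant) {
  switch(task_variant,
    one_button = 1L,
    two_button = 2L,
    four_button = 4L,
    stop("unknown task variant: ", task_variant, call. = FALSE)
  )
}

validate_task_config <- function(cfg) {
  if (!inherits(cfg, "task_config")) {
    stop("not a task_config object", call. = FALSE)
  }
  bad <- function(msg) stop("invalid task configuration: ", msg, call. = FALSE)
  if (cfg$hold_time_ms <= 0L) bad("hold_time_ms must be > 0")
  if (cfg$timeout_ms < 0L) bad("timeout_ms must be >= 0")
  if (cfg$session_cap_ms <= 0L) bad("session_cap_ms must be > 0")
  if (cfg$refractory_ms < 0L) bad("refractory_ms must be >= 0")
  if (cfg$n_buttons < active_buttons(cfg$task_variant)) {
    bad("n_buttons is smaller than the active buttons of the task variant")
  }
  if (is.na(cfg$rng_seed)) bad("rng_seed must be an integer")
  cfg
}

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config>\n")
  cat(sprintf("  variant: %s (%d of %d buttons active)\n",
              x$task_variant, active_buttons(x$task_variant), x$n_buttons))
  cat(sprintf("  hold time: %d ms | time-out: %d ms (%s)\n",
              x$hold_time_ms, x$timeout_ms, x$timeout_prolong))
  cat(sprintf("  session cap: %.1f min | seed: %d\n",
              x$session_cap_ms / 60000, x$rng_seed))
  invisible(x)
}

# Serialize/deserialize a task_config as flat key=value pairs (used both by
# the log-file header and the YAML configuration files).
task_config_fields <- function() {
  c("task_variant", "n_buttons", "hold_time_ms", "timeout_ms",
    "timeout_prolong", "session_cap_ms", "reward_units_per_success",
    "refractory_ms", "rng_seed")
}

task_config_from_list <- function(lst) {
  known <- task_config_fields()
  args <- lst[intersect(names(lst), known)]
  do.call(task_config, args)
}

#' Read task and protocol configuration from a YAML file
#'
#' The file is a flat mapping whose keys are the fields of [task_config()]
#' and [protocol_config()]; unknown keys are an error.
#'
#' @param path Path to a YAML configuration file.
#' @return A list with elements `task` ([task_config()]) and `protocol`
#'   ([protocol_config()]).
#' @export
read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lst <- yaml::read_yaml(path)
  if (!is.list(lst)) stop("config file is not a key-value mapping", call. = FALSE)
  known <- c(task_config_fields(), protocol_config_fields())
  unknown <- setdiff(names(lst), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  list(
    task = task_config_from_list(lst),
    protocol = protocol_config_from_list(lst)
  )
}
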