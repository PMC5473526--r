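test_that("session initialisation lights a cue and is reproducible", {
  cfg <- task_config(task_variant = "four_button", rng_seed = 1)
  st <- init_session(cfg)
  expect_s3_class(st, "engine_state")
  expect_true(st$cue %in% 1:4)
  expect_identical(st$clock_ms, 0L)
  expect_true(is.na(st$timeout_until_ms))

  # one-button task: any press is rewardable, cue carries "any" semantics
  st1 <- init_session(task_config(task_variant = "one_button", rng_seed = 1))
  expect_identical(st1$cue, 0L)

  expect_identical(init_session(cfg), init_session(cfg))
})

test_that("press scoring implements the hold/wrong-button/early-release rules", {
  cfg <- task_config(task_variant = "four_button", hold_time_ms = 50,
                     rng_seed = 7)
  st <- init_session(cfg)
  st$cue <- 2L

  hold_ok <- score_press(st, press_attempt(2, 1000, 50), cfg)
  expect_identical(hold_ok$record$outcome, "SUCCESS")
  expect_true(hold_ok$record$reward)

  too_short <- score_press(st, press_attempt(2, 1000, 49), cfg)
  expect_identical(too_short$record$outcome, "EARLY_RELEASE")
  expect_false(too_short$record$reward)
  # the same cue re-illuminates after the error
  expect_identical(too_short$state$cue, 2L)

  wrong <- score_press(st, press_attempt(3, 1000, 200), cfg)
  expect_identical(wrong$record$outcome, "WRONG_BUTTON")
  expect_identical(wrong$state$cue, 2L)
  expect_false(is.na(wrong$state$timeout_until_ms))

  # one-button task rewards any button held long enough
  cfg1 <- task_config(task_variant = "one_button", rng_seed = 7)
  st1 <- init_session(cfg1)
  any_btn <- score_press(st1, press_attempt(4, 500, 60), cfg1)
  expect_identical(any_btn$record$outcome, "SUCCESS")
})

test_that("presses during a time-out are scored TIMEOUT_PRESS and prolong it", {
  cfg <- task_config(task_variant = "four_button", timeout_ms = 3000,
                     timeout_prolong = "restart", rng_seed = 3)
  st <- init_session(cfg)
  st$cue <- 2L
  # wrong button at t=1000 held 100 ms -> time-out from release (1100)
  r1 <- score_press(st, press_attempt(3, 1000, 100), cfg)
  expect_identical(r1$state$timeout_until_ms, 1100L + 3000L)

  # press 1 ms after the error release: still inside the time-out
  r2 <- score_press(r1$state, press_attempt(2, 1101, 80), cfg)
  expect_identical(r2$record$outcome, "TIMEOUT_PRESS")
  # restart: the full time-out restarts from this press's release
  expect_identical(r2$state$timeout_until_ms, 1101L + 80L + 3000L)

  # a press a full time-out later is scored normally against the same cue
  r3 <- score_press(r2$state, press_attempt(2, r2$state$timeout_until_ms, 60),
                    cfg)
  expect_identical(r3$record$outcome, "SUCCESS")
  expect_identical(r3$record$cued_button, 2L)

  # under "extend", each press appends one period to the pending time-out
  cfg_e <- task_config(task_variant = "four_button", timeout_ms = 3000,
                       timeout_prolong = "extend", rng_seed = 3)
  st_e <- init_session(cfg_e)
  st_e$cue <- 2L
  e1 <- score_press(st_e, press_attempt(3, 1000, 100), cfg_e)
  e2 <- score_press(e1$state, press_attempt(2, 1101, 80), cfg_e)
  expect_identical(e2$state$timeout_until_ms, 1100L + 3000L + 3000L)
})

test_that("run_session replays scripts, drops post-cap presses, and is deterministic", {
  cfg <- task_config(task_variant = "one_button", session_cap_ms = 60000,
                     rng_seed = 5)
  expect_identical(nrow(run_session(cfg, data.frame(button = integer(0),
                                                    t_down_ms = integer(0),
                                                    duration_ms = integer(0)))$trials),
                   0L)

  script <- data.frame(button = 1L, t_down_ms = seq(0, 40000, by = 10000),
                       duration_ms = 60L)
  log <- run_session(cfg, script)
  expect_identical(log$trials$outcome, rep("SUCCESS", 5L))

  # a press beyond the cap is dropped, not scored
  over <- rbind(script, data.frame(button = 1L, t_down_ms = 61000,
                                   duration_ms = 60L))
  expect_identical(nrow(run_session(cfg, over)$trials), 5L)

  # and score_press signals session-over for it
  st <- init_session(cfg)
  expect_error(score_press(st, press_attempt(1, 61000, 60), cfg),
               class = "autoprt_session_over")

  cfg4 <- task_config(task_variant = "four_button", session_cap_ms = 1e6,
                      rng_seed = 11)
  script4 <- random_script(30)
  expect_identical(run_session(cfg4, script4), run_session(cfg4, script4))

  expect_error(run_session(cfg, data.frame(button = 1, t_down_ms = c(100, 50),
                                           duration_ms = 60)),
               "unordered")
})

test_that("post-success cue selection is uniform over active buttons", {
  cfg <- task_config(task_variant = "four_button", rng_seed = 123)
  st <- init_session(cfg)
  draws <- integer(10000)
  for (i in seq_along(draws)) {
    nxt <- select_next_cue(st, cfg)
    draws[i] <- nxt$cue
    st <- nxt$state
  }
  freq <- tabulate(draws, 4) / length(draws)
  expect_true(all(abs(freq - 0.25) < 0.02))

  # fixed seed -> reproducible draw sequence
  st_a <- init_session(cfg)
  st_b <- init_session(cfg)
  seq_a <- replicate(50, {
    nxt <- select_next_cue(st_a, cfg); st_a <<- nxt$state; nxt$cue
  })
  seq_b <- replicate(50, {
    nxt <- select_next_cue(st_b, cfg); st_b <<- nxt$state; nxt$cue
  })
  expect_identical(seq_a, seq_b)

  cfg1 <- task_config(task_variant = "one_button", rng_seed = 123)
  expect_identical(select_next_cue(init_session(cfg1), cfg1)$cue, 0L)
})

test_that("engine invariants hold over random press scripts", {
  set.seed(42)
  for (i in 1:150) {
    variant <- if (i %% 2) "four_button" else "one_button"
    script <- random_script(n = sample(5:60, 1))
    cap <- max(script$t_down_ms + script$duration_ms) + 1000L
    cfg <- task_config(task_variant = variant, session_cap_ms = cap,
                       rng_seed = i)
    log <- run_session(cfg, script)
    tr <- log$trials

    # conservation: every attempt is scored with exactly one outcome
    expect_identical(nrow(tr), nrow(script))
    expect_identical(sum(table(factor(tr$outcome, levels = c(
      "SUCCESS", "WRONG_BUTTON", "EARLY_RELEASE", "TIMEOUT_PRESS")))),
      nrow(tr))

    # cue persistence: the cue is constant between an error and the next
    # success (cue changes only ever follow a SUCCESS row)
    if (nrow(tr) > 1) {
      changed <- which(diff(tr$cued_button) != 0)
      expect_true(all(tr$outcome[changed] == "SUCCESS"))
    }

    # time-out semantics: no press within timeout_ms of an error's release
    # is scored as anything but TIMEOUT_PRESS (restart prolongation)
    if (nrow(tr) > 1) {
      release <- tr$t_down_ms + tr$duration_ms
      err <- tr$outcome != "SUCCESS"
      for (j in which(err[-nrow(tr)])) {
        inside <- which(tr$t_down_ms > release[j] &
                          tr$t_down_ms < release[j] + cfg$timeout_ms)
        inside <- inside[inside > j]
        if (length(inside)) {
          expect_true(all(tr$outcome[inside] == "TIMEOUT_PRESS"))
        }
      }
    }
  }
})

test_that("raising the hold time never increases successes on the any-cue task", {
  set.seed(99)
  for (i in 1:100) {
    script <- random_script(n = sample(5:50, 1))
    cap <- max(script$t_down_ms + script$duration_ms) + 1000L
    counts <- vapply(c(30L, 50L, 80L, 120L), function(h) {
      n_successes(run_session(
        task_config(task_variant = "one_button", hold_time_ms = h,
                    session_cap_ms = cap, rng_seed = i),
        script))
    }, integer(1))
    expect_true(all(diff(counts) <= 0L))
  }
})
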