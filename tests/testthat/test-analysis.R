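test_that("session metrics compute rates and handle the empty session", {
  log <- stub_log(60, others = 40, duration_min = 30)
  m <- session_metrics(log)
  expect_equal(m$cp_per_hr, 120)
  expect_equal(m$pct_correct, 60)
  expect_identical(m$attempts, 100L)

  empty <- stub_log(0, duration_min = 30)
  m0 <- session_metrics(empty)
  expect_equal(m0$cp_per_hr, 0)
  expect_true(is.na(m0$pct_correct))  # undefined, not zero

  # early releases keep % correct below 100 even on the one-button task
  rel <- stub_log(10, others = 5, task_variant = "one_button")
  expect_lt(session_metrics(rel)$pct_correct, 100)

  # time-out presses can be excluded from the attempt denominator
  to <- stub_log(10, others = 10, other_outcome = "TIMEOUT_PRESS")
  expect_equal(session_metrics(to)$pct_correct, 50)
  expect_equal(session_metrics(to, include_timeout_presses = FALSE)$pct_correct,
               100)
})

test_that("breeding-facility classification follows the 30-success rule", {
  rule <- classification_rule()
  expect_identical(classify_bf(list(stub_log(12), stub_log(30), stub_log(4)),
                               rule), "USER")
  expect_identical(classify_bf(list(stub_log(29), stub_log(29)), rule),
                   "NON_USER")
  expect_identical(classify_bf(list(), rule), "UNEXPOSED")
  expect_error(classify_bf(list(stub_log(10, facility = "RF"))),
               "breeding-facility")

  # monotone: more sessions can promote NON_USER -> USER, never demote
  set.seed(3)
  for (i in 1:25) {
    logs <- lapply(sample(0:35, sample(1:6, 1), replace = TRUE), stub_log)
    before <- classify_bf(logs)
    after <- classify_bf(c(logs, list(stub_log(sample(0:35, 1)))))
    if (before == "USER") expect_identical(after, "USER")
  }
})

test_that("sessions-to-criterion finds the first qualifying session", {
  logs <- function(counts) {
    lapply(seq_along(counts), function(i) {
      stub_log(counts[i], facility = "RF", session_index = i)
    })
  }
  expect_identical(sessions_to_criterion(logs(c(150, 3))), 1L)
  expect_identical(sessions_to_criterion(logs(c(10, 99, 100))), 3L)
  expect_identical(sessions_to_criterion(logs(c(10, 99))), NA_integer_)

  # non-increasing as the threshold decreases
  cnt <- c(5, 40, 80, 120, 200)
  s <- sapply(c(200, 120, 80, 40, 5), function(th) {
    sessions_to_criterion(logs(cnt), th)
  })
  expect_true(all(diff(s) <= 0))
})

test_that("analysis windows slice sessions relative to their anchors", {
  rf <- lapply(1:30, function(i) {
    stub_log(10, facility = "RF", session_index = i,
             task_variant = if (i >= 9) "four_button" else "one_button")
  })
  main <- select_window(rf, builtin_window("rf_main"))
  expect_length(main, 23)  # sessions 5..27 inclusive
  expect_identical(range(sapply(main, function(l) l$session_index)),
                   c(5L, 27L))

  # four-button onset at session 9 -> sessions 9..21
  fb <- select_window(rf, builtin_window("rf_4b"))
  expect_identical(range(sapply(fb, function(l) l$session_index)),
                   c(9L, 21L))

  lab <- lapply(1:8, function(i) {
    stub_log(5, facility = "LAB", session_index = i)
  })
  expect_length(select_window(lab, builtin_window("lab_early")), 8)

  # anchor absent
  expect_error(select_window(lab, builtin_window("rf_main")), "anchor absent")
  only_1b <- rf[1:5]
  expect_error(select_window(only_1b, builtin_window("rf_4b")),
               "never reached")
})

test_that("group summaries average within subject first, then over subjects", {
  # two USER subjects with *different* session counts: SE must be over the
  # 2 subjects, not the 5 sessions
  logs <- c(
    lapply(1:2, function(i) stub_log(60, others = 0, facility = "RF",
                                     session_index = i, subject_id = "A",
                                     duration_min = 60)),
    lapply(1:3, function(i) stub_log(c(30, 60, 90)[i], facility = "RF",
                                     session_index = i, subject_id = "B",
                                     duration_min = 60))
  )
  subjects <- data.frame(subject_id = c("A", "B"),
                         housing_group = 1L, archetype = "USER",
                         bf_class = "USER", stringsAsFactors = FALSE)
  cohort <- cohort_dataset(subjects, logs)
  gs <- group_summary(cohort, window_spec("all", "RF", "arrival", 1, 10),
                      measure = "cp_hr")
  # subject means: A = 60/h, B = 60/h -> group mean 60, SE over n=2 subjects
  expect_equal(gs$groups$mean, 60)
  expect_equal(gs$groups$se, 0)
  expect_identical(gs$groups$n_subjects, 2L)

  # single-subject group: SE undefined (flagged NA)
  solo <- cohort_dataset(subjects[1, ], logs[1:2])
  gs1 <- group_summary(solo, window_spec("all", "RF", "arrival", 1, 10),
                       measure = "cp_hr")
  expect_true(is.na(gs1$groups$se))

  # hand-computed mean for unequal subjects
  logs2 <- c(logs[1:2],
             lapply(1:2, function(i) stub_log(120, facility = "RF",
                                              session_index = i,
                                              subject_id = "B",
                                              duration_min = 60)))
  cohort2 <- cohort_dataset(subjects, logs2)
  gs2 <- group_summary(cohort2, window_spec("all", "RF", "arrival", 1, 10),
                       measure = "cp_hr")
  expect_equal(gs2$groups$mean, mean(c(60, 120)))
  expect_equal(gs2$groups$se, stats::sd(c(60, 120)) / sqrt(2))

  # unclassified cohort is refused
  subjects_na <- subjects; subjects_na$bf_class <- NA_character_
  expect_error(group_summary(cohort_dataset(subjects_na, logs),
                             window_spec("all", "RF", "arrival", 1, 10)),
               "classified")

  # learning curves: one row per group per session present
  expect_identical(nrow(gs$curves), 3L)
})
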