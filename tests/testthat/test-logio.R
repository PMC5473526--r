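test_that("session logs round-trip exactly through the CSV dialect", {
  log <- random_session_log(1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_session_log(log, path)
  expect_identical(read_session_log(path), log)

  # minimal one-trial log: complete header + one data row
  cfg <- task_config(task_variant = "one_button", session_cap_ms = 60000,
                     rng_seed = 2)
  one <- run_session(cfg, data.frame(button = 1, t_down_ms = 100,
                                     duration_ms = 60))
  write_session_log(one, path)
  lines <- readLines(path)
  expect_identical(sum(startsWith(lines, "#")), 15L)
  expect_identical(length(lines), 15L + 1L + 1L)
  expect_identical(read_session_log(path), one)
})

test_that("writing refuses logs that violate invariants", {
  log <- stub_log(5)
  path <- withr::local_tempfile(fileext = ".csv")
  # duration exceeding the configured cap
  bad <- log
  bad$actual_duration_ms <- bad$config$session_cap_ms + 1L
  expect_error(write_session_log(bad, path), "exceeds the session cap")
  # reward flag inconsistent with outcome
  bad2 <- log
  bad2$trials$reward[1] <- FALSE
  expect_error(write_session_log(bad2, path), "reward")
})

test_that("the reader is strict about the dialect but tolerant of extras", {
  log <- random_session_log(2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_session_log(log, path)
  lines <- readLines(path)

  # extra trailing newline: accepted
  writeLines(c(lines, ""), path)
  expect_identical(read_session_log(path), log)

  # unknown header keys are preserved in the annotation
  writeLines(c("#device_firmware=2.1", lines), path)
  got <- read_session_log(path)
  expect_match(got$annotation, "device_firmware=2.1")

  # unknown outcome token -> parse error with line number
  body_at <- which(!startsWith(lines, "#"))[1] + 1L
  if (!is.na(body_at) && body_at <= length(lines)) {
    broken <- lines
    broken[body_at] <- sub(",(SUCCESS|WRONG_BUTTON|EARLY_RELEASE|TIMEOUT_PRESS),",
                           ",MYSTERY,", broken[body_at])
    writeLines(broken, path)
    expect_error(read_session_log(path), "unknown outcome token")
  }

  # malformed row arity
  writeLines(c(lines, "not,enough,fields"), path)
  expect_error(read_session_log(path), "expected 7")

  # non-monotone press times
  hdr_n <- sum(startsWith(lines, "#")) + 1L
  log3 <- run_session(task_config(task_variant = "one_button",
                                  session_cap_ms = 60000, rng_seed = 3),
                      data.frame(button = 1, t_down_ms = c(100, 5000),
                                 duration_ms = 60))
  write_session_log(log3, path)
  l3 <- readLines(path)
  writeLines(c(l3[1:hdr_n], l3[hdr_n + 2], l3[hdr_n + 1]), path)
  expect_error(read_session_log(path), "non-decreasing|timestamp")
})

test_that("round-trip identity holds over randomized valid logs", {
  path <- withr::local_tempfile(fileext = ".csv")
  for (seed in 1:60) {
    log <- random_session_log(seed)
    write_session_log(log, path)
    expect_identical(read_session_log(path), log)
  }
})

test_that("cohort merging enforces subject and contiguity invariants", {
  dir <- withr::local_tempdir()
  subjects <- data.frame(subject_id = c("S01", "S02"), housing_group = 1L,
                         archetype = "unknown", bf_class = NA_character_,
                         stringsAsFactors = FALSE)
  mk <- function(sid, fac, idx) {
    log <- stub_log(10, facility = fac, session_index = idx, subject_id = sid)
    f <- file.path(dir, sprintf("%s_%s_%03d.csv", sid, fac, idx))
    write_session_log(log, f)
    f
  }
  files <- c(mk("S01", "RF", 1), mk("S01", "RF", 2), mk("S01", "RF", 3),
             mk("S02", "RF", 1), mk("S02", "RF", 2), mk("S02", "RF", 3))
  ds <- merge_cohort(files, subjects)
  expect_length(ds$logs, 6)

  # missing session 2 of 3 -> contiguity error
  expect_error(merge_cohort(files[c(1, 3)], subjects), "contiguous")

  # duplicate (subject, facility, index) -> duplicate error
  expect_error(merge_cohort(c(files, files[1]), subjects), "duplicate")

  # orphan subject id -> error naming it
  expect_error(merge_cohort(files, subjects[1, ]), "S02")
})

test_that("cohort bundles round-trip through a directory", {
  cohort <- simulate_cohort(cohort_spec(
    n_users = 1, n_non_users = 1, n_unexposed = 1,
    bf_group_sessions = 1, bf_individual_sessions = 2,
    rf_sessions = 3, lab_sessions = 2, rf_cap_min = 10,
    bf_group_cap_min = 10, bf_individual_cap_min = 10, master_seed = 55
  ))
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "subjects.csv")))
  back <- read_cohort(dir)
  expect_identical(length(back$logs), length(cohort$logs))
  expect_identical(back$subjects$subject_id, cohort$subjects$subject_id)
  expect_identical(back$subjects$bf_class, cohort$subjects$bf_class)
  expect_equal(back$provenance$master_seed, cohort$provenance$master_seed)
  # logs identical after matching on (subject, facility, index)
  key <- function(l) sprintf("%s_%s_%d", l$subject_id, l$facility,
                             l$session_index)
  lut <- stats::setNames(cohort$logs, vapply(cohort$logs, key, character(1)))
  for (l in back$logs) expect_identical(l, lut[[key(l)]])
})
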