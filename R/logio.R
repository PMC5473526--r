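#' Write a session log to the canonical CSV dialect
#'
#' The on-disk format mirrors what the training devices store on their
#' memory card: a UTF-8 CSV whose header lines are `#key=value` pairs (the
#' session metadata and the complete task-parameter echo), followed by the
#' column header
#' `timestamp,cued_button,pressed_button,t_down_ms,duration_ms,outcome,reward`
#' and one row per scored press. Timestamps are ISO-8601 with millisecond
#' precision, derived from the session start datetime plus `t_down_ms`;
#' `cued_button` is `any` on the one-button task; `reward` is
#' `true`/`false`. The log is validated before writing and invalid logs
#' are refused.
#'
#' @param log A [session_log()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(log, path) {
  validate_session_log(log)
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  hdr <- c(
    subject_id = log$subject_id,
    facility = log$facility,
    session_index = log$session_index,
    datetime = log$datetime,
    task_variant = log$config$task_variant,
    n_buttons = log$config$n_buttons,
    hold_time_ms = log$config$hold_time_ms,
    timeout_ms = log$config$timeout_ms,
    timeout_prolong = log$config$timeout_prolong,
    session_cap_ms = log$config$session_cap_ms,
    reward_units_per_success = log$config$reward_units_per_success,
    refractory_ms = log$config$refractory_ms,
    rng_seed = log$config$rng_seed,
    actual_duration_ms = log$actual_duration_ms,
    annotation = log$annotation
  )
  writeLines(sprintf("#%s=%s", names(hdr), as.character(hdr)), con)
  writeLines("timestamp,cued_button,pressed_button,t_down_ms,duration_ms,outcome,reward",
             con)
  tr <- log$trials
  if (nrow(tr)) {
    start <- parse_iso8601(log$datetime)
    writeLines(sprintf(
      "%s,%s,%d,%d,%d,%s,%s",
      format_iso8601(start, ms = tr$t_down_ms),
      ifelse(tr$cued_button == CUE_ANY, "any", as.character(tr$cued_button)),
      tr$pressed_button, tr$t_down_ms, tr$duration_ms, tr$outcome,
      ifelse(tr$reward, "true", "false")
    ), con)
  }
  invisible(path)
}

#' Read a session log from the canonical CSV dialect
#'
#' Strict parser for the format written by [write_session_log()]: malformed
#' rows, unknown outcome tokens, inconsistent reward flags and
#' non-monotone timestamps are errors reporting the offending line number.
#' Unknown `#key=value` header lines are preserved by appending them to
#' the annotation field. A trailing newline is tolerated.
#'
#' @param path Input file path.
#' @return A validated [session_log()].
#' @export
read_session_log <- function(path) {
  if (!file.exists(path)) stop("no such log file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  perr <- function(i, msg) {
    stop(sprintf("%s:%d: %s", path, i, msg), call. = FALSE)
  }

  hdr <- list()
  extra <- character(0)
  i <- 1L
  while (i <= length(lines) && startsWith(lines[[i]], "#")) {
    kv <- sub("^#", "", lines[[i]])
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 1L) perr(i, "malformed header line (expected #key=value)")
    key <- substr(kv, 1L, eq - 1L)
    val <- substr(kv, eq + 1L, nchar(kv))
    known <- c("subject_id", "facility", "session_index", "datetime",
               "actual_duration_ms", "annotation", task_config_fields())
    if (key %in% known) {
      hdr[[key]] <- val
    } else {
      extra <- c(extra, paste0(key, "=", val))
    }
    i <- i + 1L
  }
  expect_cols <- "timestamp,cued_button,pressed_button,t_down_ms,duration_ms,outcome,reward"
  if (i > length(lines) || !identical(lines[[i]], expect_cols)) {
    perr(min(i, length(lines)), "missing or malformed column header")
  }
  required <- c("subject_id", "facility", "session_index", "datetime",
                "actual_duration_ms", "task_variant", "hold_time_ms")
  miss <- setdiff(required, names(hdr))
  if (length(miss)) {
    perr(1L, paste("missing header key(s):", paste(miss, collapse = ", ")))
  }

  int_field <- function(key, default = NULL) {
    if (is.null(hdr[[key]])) return(default)
    v <- suppressWarnings(as.integer(hdr[[key]]))
    if (is.na(v)) perr(1L, paste("non-integer header value for", key))
    v
  }
  config <- task_config(
    task_variant = hdr$task_variant,
    n_buttons = int_field("n_buttons", 4L),
    hold_time_ms = int_field("hold_time_ms"),
    timeout_ms = int_field("timeout_ms", 3000L),
    timeout_prolong = hdr$timeout_prolong %||% "restart",
    session_cap_ms = int_field("session_cap_ms",
                               int_field("actual_duration_ms")),
    reward_units_per_success = as.numeric(hdr$reward_units_per_success %||% 1),
    refractory_ms = int_field("refractory_ms", 0L),
    rng_seed = int_field("rng_seed", 1L)
  )

  body <- lines[seq.int(i + 1L, length.out = max(0L, length(lines) - i))]
  body_lineno <- seq.int(i + 1L, length.out = length(body))
  # a final empty element = extra trailing newline; tolerated
  if (length(body) && !nzchar(body[length(body)])) {
    body <- body[-length(body)]
    body_lineno <- body_lineno[-length(body_lineno)]
  }
  n <- length(body)
  cued <- integer(n); pressed <- integer(n); t0 <- integer(n)
  dur <- integer(n); outc <- character(n); rew <- logical(n)
  stamps <- character(n)
  for (j in seq_len(n)) {
    ln <- body_lineno[[j]]
    parts <- strsplit(body[[j]], ",", fixed = TRUE)[[1L]]
    if (length(parts) != 7L) perr(ln, "expected 7 comma-separated fields")
    stamps[j] <- parts[[1L]]
    cued[j] <- if (identical(parts[[2L]], "any")) CUE_ANY else {
      v <- suppressWarnings(as.integer(parts[[2L]]))
      if (is.na(v)) perr(ln, "invalid cued_button")
      v
    }
    pressed[j] <- suppressWarnings(as.integer(parts[[3L]]))
    t0[j] <- suppressWarnings(as.integer(parts[[4L]]))
    dur[j] <- suppressWarnings(as.integer(parts[[5L]]))
    if (is.na(pressed[j]) || is.na(t0[j]) || is.na(dur[j])) {
      perr(ln, "non-integer press fields")
    }
    if (!parts[[6L]] %in% OUTCOMES) {
      perr(ln, paste("unknown outcome token:", parts[[6L]]))
    }
    outc[j] <- parts[[6L]]
    if (!parts[[7L]] %in% c("true", "false")) {
      perr(ln, "reward must be true or false")
    }
    rew[j] <- identical(parts[[7L]], "true")
    if (rew[j] != (outc[j] == "SUCCESS")) {
      perr(ln, "reward flag inconsistent with outcome")
    }
  }
  if (n > 1L && is.unsorted(t0)) {
    perr(body_lineno[[which(diff(t0) < 0)[1L] + 1L]],
         "timestamps not non-decreasing")
  }
  # cross-check the redundant timestamp column against datetime + offset
  if (n > 0L) {
    start <- parse_iso8601(hdr$datetime)
    expect <- format_iso8601(start, ms = t0)
    bad <- which(stamps != expect)
    if (length(bad)) {
      perr(body_lineno[[bad[[1L]]]],
           "timestamp inconsistent with session datetime + t_down_ms")
    }
  }

  annotation <- hdr$annotation %||% ""
  if (length(extra)) {
    annotation <- paste(c(annotation[nzchar(annotation)], extra),
                        collapse = "; ")
  }
  session_log(
    subject_id = hdr$subject_id, facility = hdr$facility,
    session_index = int_field("session_index"), datetime = hdr$datetime,
    config = config, actual_duration_ms = int_field("actual_duration_ms"),
    annotation = annotation,
    trials = data.frame(
      cued_button = cued, pressed_button = pressed, t_down_ms = t0,
      duration_ms = dur, outcome = outc, reward = rew,
      stringsAsFactors = FALSE
    )
  )
}

session_log_filename <- function(log) {
  sprintf("%s_%s_%03d.csv", log$subject_id, log$facility, log$session_index)
}

#' Merge session-log files and a subject table into a cohort dataset
#'
#' Reads every log file, attaches the subject metadata and verifies the
#' dataset invariants: all logs belong to a listed subject, no duplicate
#' (subject, facility, index) triple, and per-facility indices contiguous
#' from 1.
#'
#' @param log_files Character vector of session-log paths.
#' @param subject_table Data frame with at least a `subject_id` column
#'   (typically the `subjects.csv` of a cohort bundle).
#' @return A [cohort_dataset()].
#' @export
merge_cohort <- function(log_files, subject_table) {
  logs <- lapply(log_files, read_session_log)
  cohort_dataset(subject_table, logs)
}

#' Write a cohort bundle to a directory
#'
#' One CSV per session (`<subject>_<facility>_<index>.csv`), a
#' `subjects.csv` with the subject metadata, and a `provenance.json`.
#'
#' @param cohort A [cohort_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (log in cohort$logs) {
    write_session_log(log, file.path(dir, session_log_filename(log)))
  }
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$provenance,
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort bundle written by [write_cohort()]
#' @param dir Bundle directory.
#' @return A [cohort_dataset()].
#' @export
read_cohort <- function(dir) {
  subj_path <- file.path(dir, "subjects.csv")
  if (!file.exists(subj_path)) {
    stop("not a cohort bundle (no subjects.csv): ", dir, call. = FALSE)
  }
  subjects <- utils::read.csv(subj_path, stringsAsFactors = FALSE)
  files <- list.files(dir, pattern = "^.+_(BF|RF|LAB)_[0-9]+\\.csv$",
                      full.names = TRUE)
  if (!length(files)) stop("no session logs found in ", dir, call. = FALSE)
  prov_path <- file.path(dir, "provenance.json")
  prov <- if (file.exists(prov_path)) {
    jsonlite::read_json(prov_path, simplifyVector = TRUE)
  } else {
    list()
  }
  ds <- merge_cohort(files, subjects)
  ds$provenance <- prov
  ds
}
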