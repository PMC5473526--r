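#' @keywords internal
"_PACKAGE"

# Round half away from zero (base round() is banker's rounding).
round_half_up <- function(x) {
  floor(x + 0.5)
}

# Deterministic 31-bit sub-seed from a master seed and a label path.
# Polynomial string hash; kept below 2^31 - 1 so it is a valid R seed and
# all intermediate products stay exactly representable in doubles.
derive_seed <- function(master_seed, ...) {
  labels <- paste(c(...), collapse = "/")
  h <- as.numeric(master_seed) %% 2147483647
  for (code in utf8ToInt(labels)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr with the global RNG temporarily seeded/restored, so package
# internals never disturb the caller's random stream.
with_preserved_rng <- function(expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

get_rng_state <- function() {
  get(".Random.seed", envir = globalenv())
}

set_rng_state <- function(state) {
  assign(".Random.seed", state, envir = globalenv())
}

# ISO-8601 helpers. Session headers carry whole-second UTC datetimes;
# per-trial timestamps add the within-session millisecond offset.
parse_iso8601 <- function(x) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  if (any(is.na(out))) {
    stop("invalid ISO-8601 datetime: ", paste(x[is.na(out)], collapse = ", "),
         call. = FALSE)
  }
  out
}

format_iso8601 <- function(t, ms = NULL) {
  if (is.null(ms)) {
    format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  } else {
    paste0(format(t + ms %/% 1000, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
           sprintf(".%03dZ", ms %% 1000))
  }
}

# Sequence of n working-day dates (Mon-Fri) starting at or after `from`.
working_days <- function(from, n) {
  out <- as.Date(character(0))
  d <- as.Date(from)
  while (length(out) < n) {
    if (!format(d, "%u") %in% c("6", "7")) out <- c(out, d)
    d <- d + 1
  }
  out
}

# 32-bit FNV-1a checksum of a character scalar, reported as 8 hex digits.
# Used for manifest/provenance fingerprints of configuration objects.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 2166136261
  for (code in utf8ToInt(x)) {
    # xor with a byte only touches the low 8 bits; keeps h a double in range
    low <- h %% 256
    h <- (h - low) + bitwXor(as.integer(low), as.integer(code))
    # 32-bit multiply by the FNV prime 16777619, done in two 16-bit halves
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  # h may exceed .Machine$integer.max; render hex from the two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
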