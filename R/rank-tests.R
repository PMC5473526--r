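#' Exact Mann-Whitney U test by full enumeration
#'
#' Rank-sum test for two independent samples, reported with the convention
#' used for small behavioural samples: the statistic is
#' \eqn{U = \min(U_x, U_y)} computed on mid-ranks, and the two-sided
#' p-value is the exact probability, over all
#' \eqn{\binom{n_x + n_y}{n_x}} equally likely group assignments of the
#' pooled observations, that \eqn{\min(U_x, U_y)} is at most the observed
#' value. Ties are handled exactly: mid-ranks are fixed by the pooled data
#' and the enumeration permutes them.
#'
#' When the number of assignments exceeds `max_enumeration` the p-value
#' falls back to the normal approximation with tie-corrected variance and
#' continuity correction (the result notes which route was taken).
#'
#' @param x,y Numeric vectors (each non-empty).
#' @param max_enumeration Largest assignment count for which the exact
#'   enumeration is used (default `1e6`).
#' @return An object of class `htest` with `statistic` (U), `p.value`, and
#'   a `method` string recording exact vs approximate.
#' @examples
#' mann_whitney_exact(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mann_whitney_exact <- function(x, y, max_enumeration = 1e6) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  ux <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  uy <- nx * ny - ux
  u <- min(ux, uy)

  n_assign <- choose(n, nx)
  if (n_assign <= max_enumeration) {
    idx <- utils::combn(n, nx)
    rank_sums <- colSums(matrix(r[idx], nrow = nx))
    ux_all <- rank_sums - nx * (nx + 1) / 2
    umin_all <- pmin(ux_all, nx * ny - ux_all)
    # tolerance for half-integer mid-rank arithmetic
    p <- mean(umin_all <= u + 1e-9)
    method <- sprintf(
      "Exact Mann-Whitney U test (full enumeration of %d assignments)",
      n_assign)
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(r)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu + 0.5) / sqrt(sigma2)  # continuity-corrected, u <= mu
      p <- min(1, 2 * stats::pnorm(z))
    }
    method <- "Mann-Whitney U test (normal approximation, tie-corrected)"
  }

  structure(
    list(
      statistic = c(U = u),
      p.value = p,
      alternative = "two.sided",
      method = method,
      data.name = sprintf("x (n = %d) and y (n = %d)", nx, ny)
    ),
    class = "htest"
  )
}

#' Kruskal-Wallis rank test with tie correction
#'
#' Computes the Kruskal-Wallis statistic
#' \deqn{H = \left[\frac{12}{N(N+1)} \sum_i \frac{R_i^2}{n_i} - 3(N+1)\right]
#'   \Big/ \left[1 - \frac{\sum_t (t^3 - t)}{N^3 - N}\right]}
#' over \eqn{k \ge 2} groups and refers it to a chi-square distribution with
#' \eqn{k - 1} degrees of freedom. The chi-square reference is asymptotic;
#' with the small per-group counts typical of behavioural cohorts the
#' p-value is approximate (the same caveat applies to the source software
#' this mirrors).
#'
#' @param groups List of at least two non-empty numeric vectors.
#' @return An object of class `htest` with `statistic` (H), `parameter`
#'   (df) and `p.value`.
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups)) stop("groups must be a list of vectors", call. = FALSE)
  groups <- lapply(groups, as.numeric)
  groups <- groups[vapply(groups, length, integer(1)) > 0L]
  k <- length(groups)
  if (k < 2L) stop("need at least two non-empty groups", call. = FALSE)
  if (anyNA(unlist(groups))) stop("missing values not allowed", call. = FALSE)
  pooled <- unlist(groups, use.names = FALSE)
  n_i <- vapply(groups, length, integer(1))
  N <- length(pooled)
  r <- rank(pooled)
  grp <- rep(seq_len(k), n_i)
  R_i <- tapply(r, grp, sum)
  h_raw <- 12 / (N * (N + 1)) * sum(R_i^2 / n_i) - 3 * (N + 1)
  tie_tab <- table(r)
  correction <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  h <- if (correction <= 0) 0 else h_raw / correction  # all values tied
  p <- if (correction <= 0) 1 else stats::pchisq(h, df = k - 1, lower.tail = FALSE)
  structure(
    list(
      statistic = c(H = h),
      parameter = c(df = k - 1),
      p.value = p,
      method = "Kruskal-Wallis rank test (tie-corrected, chi-square reference)",
      data.name = sprintf("%d groups (N = %d)", k, N)
    ),
    class = "htest"
  )
}

#' Ordinary least-squares regression of one predictor
#'
#' Simple linear regression as used for practice-vs-performance analyses:
#' slope, intercept, coefficient of determination and the two-sided p-value
#' of the slope's t-test. Fitting is delegated to [stats::lm()].
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`; `x` must vary.
#' @return Object of class `prt_ols`: list with `slope`, `intercept`,
#'   `r.squared`, `p.value`, `n`.
#' @examples
#' fit <- ols_regression(1:10, 2 * (1:10) + 1)
#' fit$r.squared  # 1
#' @export
ols_regression <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (stats::var(x) == 0) stop("x is constant; slope undefined", call. = FALSE)
  if (stats::var(y) == 0) {
    # flat response: zero slope, nothing explained
    return(structure(
      list(slope = 0, intercept = y[1L], r.squared = 0, p.value = 1,
           n = length(x)),
      class = "prt_ols"
    ))
  }
  fit <- stats::lm(y ~ x)
  # exact fits are legitimate inputs; silence the perfect-fit warning
  sm <- suppressWarnings(summary(fit))
  co <- stats::coef(sm)
  # constant y: summary() leaves R^2 = 0 and the slope row has p = NA;
  # report slope 0, p = 1 in that degenerate case
  slope <- unname(stats::coef(fit)[2L])
  p <- if (nrow(co) < 2L || is.na(co[2L, 4L])) 1 else co[2L, 4L]
  structure(
    list(
      slope = slope,
      intercept = unname(stats::coef(fit)[1L]),
      r.squared = sm$r.squared,
      p.value = unname(p),
      n = length(x)
    ),
    class = "prt_ols"
  )
}

#' @export
print.prt_ols <- function(x, ...) {
  cat(sprintf("OLS fit (n = %d): y = %.4g + %.4g x | R^2 = %.4f | slope p = %.4g\n",
              x$n, x$intercept, x$slope, x$r.squared, x$p.value))
  invisible(x)
}
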