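#' Power of the classical two-sample t test
#'
#' Exact power from the noncentral t distribution: with per-group size
#' \eqn{n} and standardized effect \eqn{d}, the test statistic follows a
#' noncentral t with \eqn{2n - 2} degrees of freedom and noncentrality
#' \eqn{d\sqrt{n/2}}. Two-sided power is the mass of \eqn{|T|} beyond the
#' \eqn{1-\alpha/2} critical value, one-sided power the upper-tail mass
#' beyond the \eqn{1-\alpha} critical value.
#'
#' @param n Per-group sample size (integer, at least 2).
#' @param d Cohen's d (nonnegative).
#' @param alpha Type I error rate, in (0, 1).
#' @param sides 1 or 2.
#' @return The rejection probability.
#' @export
#' @examples
#' power_ttest(64, d = 0.5)   # ~0.80
power_ttest <- function(n, d, alpha = 0.05, sides = 2) {
  if (n < 2 || n != round(n)) stop("n must be an integer >= 2", call. = FALSE)
  if (d < 0) stop("d must be nonnegative", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (!sides %in% c(1, 2)) stop("sides must be 1 or 2", call. = FALSE)
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  if (sides == 2) {
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(tc, df, ncp, lower.tail = FALSE) + stats::pt(-tc, df, ncp)
  } else {
    tc <- stats::qt(1 - alpha, df)
    stats::pt(tc, df, ncp, lower.tail = FALSE)
  }
}

#' Classical sample size for the two-sample t test
#'
#' Smallest per-group sample size whose [power_ttest()] reaches the target
#' power, found by doubling to bracket and then bisection (power is strictly
#' increasing in n for d > 0). Deterministic and exactly minimal:
#' the returned n meets the target and n - 1 does not.
#'
#' @inheritParams power_ttest
#' @param power Target power, in (0, 1).
#' @param n_max Upper bound on the search.
#' @return The minimal per-group sample size (integer).
#' @export
#' @examples
#' ssd_freq(0.5)   # 64 per group at alpha = .05, two-sided, power .80
ssd_freq <- function(d, alpha = 0.05, power = 0.80, sides = 2,
                     n_max = 1e7) {
  if (power <= 0 || power >= 1) stop("power must lie in (0, 1)", call. = FALSE)
  ok <- function(n) power_ttest(n, d, alpha, sides) >= power
  if (ok(2)) return(2L)
  if (d == 0)
    stop("target power above alpha is unreachable when d = 0", call. = FALSE)
  lo <- 2
  repeat {
    hi <- 2 * lo
    if (hi > n_max)
      stop("target power not reached below n_max", call. = FALSE)
    if (ok(hi)) break
    lo <- hi
  }
  while (hi - lo > 1) {
    mid <- (lo + hi) %/% 2
    if (ok(mid)) hi <- mid else lo <- mid
  }
  as.integer(hi)
}
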