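#' Normal distribution of the mean difference
#'
#' Lightweight container for a univariate normal law on the difference
#' parameter \eqn{\delta = \mu_1 - \mu_2}. Both the normal approximation of
#' the posterior and the fractional prior reduce to such a law, because a
#' bivariate normal with diagonal covariance on \eqn{(\mu_1, \mu_2)} induces
#' a normal on their difference.
#'
#' @param mean Location of \eqn{\delta}.
#' @param variance Positive scale.
#' @return An object of class `"delta_dist"`.
#' @export
delta_dist <- function(mean, variance) {
  if (!is.finite(mean) || !is.finite(variance) || variance <= 0)
    stop("delta_dist needs a finite mean and a positive variance",
         call. = FALSE)
  structure(list(mean = mean, variance = variance), class = "delta_dist")
}

#' @export
print.delta_dist <- function(x, ...) {
  cat(sprintf("delta ~ N(%.6g, %.6g)\n", x$mean, x$variance))
  invisible(x)
}

#' Posterior distribution of the mean difference
#'
#' Normal approximation of the posterior of \eqn{\delta = \mu_1 - \mu_2}.
#' The posterior of each group mean is normal with the observed mean as
#' location and estimated variance divided by the group size as scale; under
#' the equal-variance model the pooled variance is used for both groups,
#' under the unequal-variance model each group keeps its own.
#'
#' @param stats A [two_group_summary()].
#' @return A [delta_dist()] with mean \eqn{\bar y_1 - \bar y_2}.
#' @export
posterior_delta <- function(stats) {
  stopifnot(inherits(stats, "two_group_summary"))
  v <- if (stats$model == "equal") {
    s2 <- pooled_variance(stats)
    s2 / stats$n1 + s2 / stats$n2
  } else {
    stats$var1 / stats$n1 + stats$var2 / stats$n2
  }
  delta_dist(stats$mean1 - stats$mean2, v)
}

#' Adjusted fractional prior of the mean difference
#'
#' The prior on \eqn{(\mu_1, \mu_2)} is a zero-centred normal whose scale is
#' calibrated by a fraction of the information in the data: with fraction
#' \eqn{b_j = m/(2 n_j)} for group \eqn{j} the per-mean prior variance is
#' \eqn{\hat\sigma_j^2 / (b_j n_j) = 2\hat\sigma_j^2/m}. Centring on zero
#' places the prior on the boundary of the null hypothesis, which makes the
#' Savage--Dickey evaluation of the equality constraint well defined. The
#' induced prior on \eqn{\delta} is \eqn{N(0,\; 2(\hat\sigma_1^2 +
#' \hat\sigma_2^2)/m)} (that is \eqn{N(0, 4\hat\sigma^2/m)} with a pooled
#' \eqn{\hat\sigma^2}).
#'
#' The default multiplier `fraction = 1` is the minimal-training-sample
#' choice (half an observation per group, one observation in total, enough
#' to identify the single contrast \eqn{\delta}); 2 and 3 are the standard
#' sensitivity variants.
#'
#' @param stats A [two_group_summary()].
#' @param fraction Integer multiplier \eqn{m \in \{1, 2, 3\}} of the base
#'   fraction \eqn{b = 1/(2n)}.
#' @return A [delta_dist()] with mean 0.
#' @export
prior_delta <- function(stats, fraction = 1) {
  stopifnot(inherits(stats, "two_group_summary"))
  fraction <- check_fraction(fraction, max(stats$n1, stats$n2))
  v <- if (stats$model == "equal") {
    4 * pooled_variance(stats) / fraction
  } else {
    2 * (stats$var1 + stats$var2) / fraction
  }
  delta_dist(0, v)
}

check_fraction <- function(fraction, n) {
  if (length(fraction) != 1L || !is.finite(fraction) ||
      fraction < 1 || fraction != round(fraction))
    stop("fraction must be a positive integer multiplier (1, 2 or 3)",
         call. = FALSE)
  if (fraction / (2 * n) > 1)
    stop("fraction m/(2n) exceeds 1; m too large for this sample size",
         call. = FALSE)
  as.integer(fraction)
}

#' Fit and complexity of the hypotheses on the mean difference
#'
#' The fit of a hypothesis is the posterior density or mass of its
#' constraint region; the complexity is the same quantity under the
#' fractional prior. For the equality constraint \eqn{\delta = 0} these are
#' densities at zero (the Savage--Dickey evaluation); for the directional
#' constraint \eqn{\delta > 0} they are tail probabilities. The complexity of
#' the directional hypothesis is exactly 1/2 for any zero-mean prior,
#' whatever its scale — the inequality constraint does not depend on the
#' prior fraction.
#'
#' @param dist A [delta_dist()] (the posterior for fits, the prior for
#'   complexities).
#' @return A nonnegative density (`fit_equality()`, `complexity_equality()`)
#'   or a probability (`fit_onesided()`, `complexity_onesided()`).
#' @name fit_complexity
NULL

#' @rdname fit_complexity
#' @export
fit_equality <- function(dist) {
  stopifnot(inherits(dist, "delta_dist"))
  stats::dnorm(0, dist$mean, sqrt(dist$variance))
}

#' @rdname fit_complexity
#' @export
complexity_equality <- function(dist) {
  stopifnot(inherits(dist, "delta_dist"))
  stats::dnorm(0, dist$mean, sqrt(dist$variance))
}

#' @rdname fit_complexity
#' @export
fit_onesided <- function(dist) {
  stopifnot(inherits(dist, "delta_dist"))
  stats::pnorm(dist$mean / sqrt(dist$variance))
}

#' @rdname fit_complexity
#' @export
complexity_onesided <- function(dist) {
  stopifnot(inherits(dist, "delta_dist"))
  if (abs(dist$mean) > 1e-12 * sqrt(dist$variance))
    stop("complexity_onesided() requires a zero-mean prior", call. = FALSE)
  0.5
}

# Vectorized log Bayes factor of H0 against the alternative, the workhorse
# behind both aafbf() and the Monte-Carlo SSD loop. All arguments except
# n1/n2/model/hypothesis/fraction may be vectors of equal length. Everything
# stays on the log scale: at large n the posterior density at 0 underflows
# long before the Bayes factor itself is extreme.
log_bf0 <- function(mean1, mean2, var1, var2, n1, n2,
                    model = "equal",
                    hypothesis = "two-sided",
                    fraction = 1L) {
  if (model == "equal") {
    s2 <- ((n1 - 1) * var1 + (n2 - 1) * var2) / (n1 + n2 - 2)
    post_v <- s2 * (1 / n1 + 1 / n2)
    prior_v <- 4 * s2 / fraction
  } else {
    post_v <- var1 / n1 + var2 / n2
    prior_v <- 2 * (var1 + var2) / fraction
  }
  dm <- mean1 - mean2
  lbf <- stats::dnorm(0, dm, sqrt(post_v), log = TRUE) -
    stats::dnorm(0, 0, sqrt(prior_v), log = TRUE)
  if (hypothesis == "one-sided") {
    # log f2 via the stable log-CDF; log c2 = log(1/2)
    lf2 <- stats::pnorm(dm / sqrt(post_v), log.p = TRUE)
    lbf <- lbf - (lf2 - log(0.5))
  }
  lbf
}

#' Approximate adjusted fractional Bayes factor for two means
#'
#' Computes the Bayes factor for the null hypothesis \eqn{H_0: \mu_1 =
#' \mu_2} against the unconstrained two-sided alternative \eqn{H_1: \mu_1
#' \neq \mu_2} or the directional alternative \eqn{H_2: \mu_1 > \mu_2},
#' from two-group summary statistics, using a normal approximation of the
#' posterior and an adjusted fractional prior centred on the null boundary.
#'
#' Each Bayes factor against the unconstrained alternative is a ratio of fit
#' over complexity, \eqn{BF_{i1} = f_i / c_i}. For \eqn{H_0} this is the
#' Savage--Dickey density ratio (posterior over prior density of \eqn{\delta
#' = \mu_1 - \mu_2} at zero, with \eqn{f_1 = c_1 = 1} since the
#' unconstrained fit and complexity integrate to one). Against the
#' directional alternative the two ratios compose, \eqn{BF_{02} = BF_{01} /
#' BF_{21}} with \eqn{BF_{21} = f_2 / c_2}, \eqn{f_2} the posterior
#' probability of \eqn{\delta > 0} and \eqn{c_2 = 1/2}. All arithmetic is
#' done on the log scale.
#'
#' @param stats A [two_group_summary()].
#' @param hypothesis `"two-sided"` (H0 vs H1) or `"one-sided"` (H0 vs H2,
#'   with H2 oriented as \eqn{\mu_1 > \mu_2}).
#' @param fraction Prior fraction multiplier, see [prior_delta()].
#' @return An object of class `"aafbf"`: a list with the fit and complexity
#'   of the equality constraint (`fit_0`, `complexity_0`), of the
#'   alternative (`fit_alt`, `complexity_alt`; both 1 two-sided, \eqn{f_2}
#'   and 1/2 one-sided), the Bayes factors `bf_0alt`, `bf_alt0`, their log
#'   `log_bf_0alt`, and the `hypothesis` and `fraction` used.
#' @export
#' @examples
#' s <- two_group_summary(100, 100, 0, 0, 1, 1)
#' aafbf(s)                          # evidence for equal means
#' aafbf(s, "one-sided", fraction = 2)
aafbf <- function(stats, hypothesis = c("two-sided", "one-sided"),
                  fraction = 1) {
  stopifnot(inherits(stats, "two_group_summary"))
  hypothesis <- match.arg(hypothesis)
  fraction <- check_fraction(fraction, max(stats$n1, stats$n2))

  post <- posterior_delta(stats)
  prior <- prior_delta(stats, fraction)
  f0 <- fit_equality(post)
  c0 <- complexity_equality(prior)
  if (hypothesis == "two-sided") {
    f_alt <- 1
    c_alt <- 1
  } else {
    f_alt <- fit_onesided(post)
    c_alt <- complexity_onesided(prior)
  }
  lbf <- log_bf0(stats$mean1, stats$mean2, stats$var1, stats$var2,
                 stats$n1, stats$n2, stats$model, hypothesis, fraction)
  structure(
    list(fit_0 = f0, complexity_0 = c0,
         fit_alt = f_alt, complexity_alt = c_alt,
         bf_0alt = exp(lbf), bf_alt0 = exp(-lbf), log_bf_0alt = lbf,
         hypothesis = hypothesis, fraction = fraction,
         model = stats$model),
    class = "aafbf"
  )
}

#' @export
print.aafbf <- function(x, ...) {
  alt <- if (x$hypothesis == "two-sided") "1" else "2"
  cat(sprintf("AAFBF, H0: mu1 = mu2 vs H%s (%s, fraction %db)\n",
              alt, x$hypothesis, x$fraction))
  cat(sprintf("  f0 = %.4g, c0 = %.4g", x$fit_0, x$complexity_0))
  if (x$hypothesis == "one-sided")
    cat(sprintf(", f%s = %.4g, c%s = %.3f", alt, x$fit_alt, alt,
                x$complexity_alt))
  cat("\n")
  cat(sprintf("  BF0%s = %.4g,  BF%s0 = %.4g\n",
              alt, x$bf_0alt, alt, x$bf_alt0))
  invisible(x)
}

#' Bayes factor from raw observations
#'
#' Convenience wrapper: [summarize_groups()] followed by [aafbf()]. The
#' Bayes factor is invariant to adding a constant to all observations and to
#' rescaling all observations by a common positive factor (the posterior and
#' prior densities at zero both scale by the reciprocal of the factor).
#'
#' @inheritParams summarize_groups
#' @inheritParams aafbf
#' @return An `"aafbf"` object, see [aafbf()].
#' @export
aafbf_raw <- function(group1, group2, model = c("equal", "unequal"),
                      hypothesis = c("two-sided", "one-sided"),
                      fraction = 1) {
  aafbf(summarize_groups(group1, group2, match.arg(model)),
        match.arg(hypothesis), fraction)
}

#' Serialize a Bayes factor result as JSON
#'
#' @param x An `"aafbf"` object.
#' @return A JSON string with keys `fit_0`, `complexity_0`, `fit_alt`,
#'   `complexity_alt`, `bf_0alt`, `bf_alt0`, `hypothesis`,
#'   `fraction_multiplier`.
#' @export
aafbf_json <- function(x) {
  stopifnot(inherits(x, "aafbf"))
  jsonlite::toJSON(
    list(fit_0 = x$fit_0, complexity_0 = x$complexity_0,
         fit_alt = x$fit_alt, complexity_alt = x$complexity_alt,
         bf_0alt = x$bf_0alt, bf_alt0 = x$bf_alt0,
         hypothesis = x$hypothesis, fraction_multiplier = x$fraction),
    auto_unbox = TRUE, digits = NA
  )
}
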