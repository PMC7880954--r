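#' Two-group summary statistics
#'
#' Container for the sufficient statistics of a two-group comparison of
#' means: per-group sample sizes, sample means and unbiased (divisor
#' \eqn{n-1}) sample variances, together with the variance model. The
#' `"equal"` model pools the two variances (classical t test); the
#' `"unequal"` model keeps them separate (Welch's test).
#'
#' @param n1,n2 Per-group sample sizes (integers, at least 2).
#' @param mean1,mean2 Sample means of groups 1 and 2.
#' @param var1,var2 Unbiased sample variances (strictly positive).
#' @param model `"equal"` for a common within-group variance, `"unequal"`
#'   for group-specific variances.
#'
#' @return An object of class `"two_group_summary"`: a list with fields
#'   `n1`, `n2`, `mean1`, `mean2`, `var1`, `var2`, `model`.
#' @seealso [summarize_groups()] to build one from raw observations,
#'   [aafbf()] to compute the Bayes factor.
#' @export
#' @examples
#' two_group_summary(n1 = 100, n2 = 100, mean1 = 0, mean2 = 0,
#'                   var1 = 1, var2 = 1)
two_group_summary <- function(n1, n2, mean1, mean2, var1, var2,
                              model = c("equal", "unequal")) {
  model <- match.arg(model)
  for (n in c(n1, n2)) {
    if (length(n) != 1L || !is.finite(n) || n < 2 || n != round(n))
      stop("group sample sizes must be integers >= 2", call. = FALSE)
  }
  vals <- c(mean1, mean2, var1, var2)
  if (length(vals) != 4L || !all(is.finite(vals)))
    stop("means and variances must be finite numbers", call. = FALSE)
  if (var1 <= 0 || var2 <= 0)
    stop("sample variances must be strictly positive (degenerate data)",
         call. = FALSE)
  structure(
    list(n1 = as.integer(n1), n2 = as.integer(n2),
         mean1 = mean1, mean2 = mean2, var1 = var1, var2 = var2,
         model = model),
    class = "two_group_summary"
  )
}

#' Summarize raw two-group observations
#'
#' Reduces two vectors of raw observations to the sufficient statistics the
#' Bayes factor depends on: arithmetic means and unbiased variances.
#'
#' @param group1,group2 Numeric vectors of observations, each with at least
#'   two finite values and nonzero spread.
#' @inheritParams two_group_summary
#' @return A [two_group_summary()] object.
#' @export
#' @examples
#' summarize_groups(c(1, 3), c(2, 2, 2, 4))
summarize_groups <- function(group1, group2, model = c("equal", "unequal")) {
  model <- match.arg(model)
  check <- function(x, lab) {
    if (!is.numeric(x) || length(x) < 2L || !all(is.finite(x)))
      stop(lab, " needs at least 2 finite numeric observations",
           call. = FALSE)
    if (stats::var(x) == 0)
      stop(lab, " has zero variance (degenerate data)", call. = FALSE)
  }
  check(group1, "group1")
  check(group2, "group2")
  two_group_summary(
    n1 = length(group1), n2 = length(group2),
    mean1 = mean(group1), mean2 = mean(group2),
    var1 = stats::var(group1), var2 = stats::var(group2),
    model = model
  )
}

#' Pooled within-group variance
#'
#' Unbiased pooled variance \eqn{((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)},
#' defined only under the equal-variance model.
#'
#' @param stats A [two_group_summary()] with `model = "equal"`.
#' @return The pooled variance (positive scalar).
#' @export
pooled_variance <- function(stats) {
  stopifnot(inherits(stats, "two_group_summary"))
  if (stats$model != "equal")
    stop("pooled_variance() is only defined for model = \"equal\"",
         call. = FALSE)
  ((stats$n1 - 1) * stats$var1 + (stats$n2 - 1) * stats$var2) /
    (stats$n1 + stats$n2 - 2)
}

#' @export
print.two_group_summary <- function(x, ...) {
  cat("Two-group summary (", x$model, " variances)\n", sep = "")
  cat(sprintf("  group 1: n = %d, mean = %.4g, var = %.4g\n",
              x$n1, x$mean1, x$var1))
  cat(sprintf("  group 2: n = %d, mean = %.4g, var = %.4g\n",
              x$n2, x$mean2, x$var2))
  invisible(x)
}
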