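#' Two-group normal population
#'
#' Describes the populations the sample-size determination simulates from:
#' observations in group \eqn{j} are i.i.d. \eqn{N(\mu_j, \sigma_j^2)}.
#' Defaults follow the common design conventions for this problem: means
#' `c(0.5, 0)` (a medium effect when the variances average to one) and
#' variances `c(1, 1)` for the equal-variance model or `c(4/3, 2/3)` for the
#' unequal-variance model.
#'
#' @param mean Numeric vector of length 2, the population means.
#' @param var Numeric vector of length 2, the population variances; `NULL`
#'   selects the model default above.
#' @param model `"equal"` (t test; variances must match) or `"unequal"`
#'   (Welch's test).
#' @return An object of class `"population_spec"` with fields `mu1`, `mu2`,
#'   `sigma2_1`, `sigma2_2`, `model`.
#' @export
#' @examples
#' population_spec()                          # d = 0.5, unit variances
#' population_spec(c(0.5, 0), model = "unequal")
population_spec <- function(mean = c(0.5, 0), var = NULL,
                            model = c("equal", "unequal")) {
  model <- match.arg(model)
  if (is.null(var))
    var <- if (model == "equal") c(1, 1) else c(4 / 3, 2 / 3)
  if (length(mean) != 2L || !all(is.finite(mean)))
    stop("mean must be two finite numbers", call. = FALSE)
  if (length(var) != 2L || !all(is.finite(var)) || any(var <= 0))
    stop("var must be two positive numbers", call. = FALSE)
  if (model == "equal" && var[1] != var[2])
    stop("model = \"equal\" requires identical population variances",
         call. = FALSE)
  structure(
    list(mu1 = mean[1], mu2 = mean[2],
         sigma2_1 = var[1], sigma2_2 = var[2], model = model),
    class = "population_spec"
  )
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf(
    "Population (%s variances): N(%.4g, %.4g) vs N(%.4g, %.4g), d = %.3f\n",
    x$model, x$mu1, x$sigma2_1, x$mu2, x$sigma2_2, cohens_d(x)))
  invisible(x)
}

#' Cohen's d of a two-group population
#'
#' Standardized mean difference \eqn{(\mu_1 - \mu_2) / \sqrt{(\sigma_1^2 +
#' \sigma_2^2)/2}}. With unit variances (or variances averaging to one, as
#' in the unequal-variance default 4/3 and 2/3) and \eqn{\mu_2 = 0}, the
#' first population mean equals d.
#'
#' @param pop A [population_spec()].
#' @return The effect size d.
#' @export
cohens_d <- function(pop) {
  stopifnot(inherits(pop, "population_spec"))
  (pop$mu1 - pop$mu2) / sqrt((pop$sigma2_1 + pop$sigma2_2) / 2)
}

# Run code under a given seed without disturbing the caller's RNG state.
# seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# Deterministic child seed for a (master seed, per-group n, population)
# stream. Streams differ across n and across the null/alternative
# populations but are shared across prior fractions, so the b/2b/3b
# sensitivity analysis is evaluated on identical simulated datasets.
child_seed <- function(seed, n, pop_id) {
  (abs(seed) %% 100000L) * 20011L + as.integer(n) * 7L + as.integer(pop_id)
}

#' Draw raw two-group data from a population
#'
#' @param pop A [population_spec()].
#' @param n Per-group sample size (at least 2).
#' @param seed Optional integer seed; when given, the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @return A list with numeric vectors `group1` and `group2` of length `n`.
#' @export
sim_raw <- function(pop, n, seed = NULL) {
  stopifnot(inherits(pop, "population_spec"))
  if (length(n) != 1L || !is.finite(n) || n < 2 || n != round(n))
    stop("n must be an integer >= 2", call. = FALSE)
  with_seed(seed, list(
    group1 = stats::rnorm(n, pop$mu1, sqrt(pop$sigma2_1)),
    group2 = stats::rnorm(n, pop$mu2, sqrt(pop$sigma2_2))
  ))
}

#' Draw batches of sufficient statistics from a population
#'
#' Samples `n_datasets` independent datasets of per-group size `n` directly
#' on the sufficient-statistic scale: sample means \eqn{\bar y_j \sim
#' N(\mu_j, \sigma_j^2/n)} and unbiased variances \eqn{s_j^2 \sim \sigma_j^2
#' \chi^2_{n-1}/(n-1)}, independently. For normal populations this is the
#' exact joint sampling distribution of the statistics the Bayes factor
#' depends on, so the batch is distributionally identical to summarizing
#' [sim_raw()] output — at O(1) rather than O(n) cost per dataset, which is
#' what makes full-size Monte-Carlo sample-size searches a desk-scale
#' computation.
#'
#' @inheritParams sim_raw
#' @param n_datasets Number of datasets to draw.
#' @return A `data.frame` of class `"sim_batch"` with columns `mean1`,
#'   `mean2`, `var1`, `var2` and attributes `n` and `model`.
#' @export
sim_suffstats <- function(pop, n, n_datasets, seed = NULL) {
  stopifnot(inherits(pop, "population_spec"))
  if (n < 2 || n != round(n)) stop("n must be an integer >= 2", call. = FALSE)
  if (n_datasets < 1) stop("n_datasets must be >= 1", call. = FALSE)
  out <- with_seed(seed, data.frame(
    mean1 = stats::rnorm(n_datasets, pop$mu1, sqrt(pop$sigma2_1 / n)),
    mean2 = stats::rnorm(n_datasets, pop$mu2, sqrt(pop$sigma2_2 / n)),
    var1 = pop$sigma2_1 * stats::rchisq(n_datasets, n - 1) / (n - 1),
    var2 = pop$sigma2_2 * stats::rchisq(n_datasets, n - 1) / (n - 1)
  ))
  attr(out, "n") <- as.integer(n)
  attr(out, "model") <- pop$model
  class(out) <- c("sim_batch", class(out))
  out
}

# Log BF01/BF02 for every dataset in a sim_batch (vectorized).
log_bf0_batch <- function(batch, hypothesis, fraction) {
  n <- attr(batch, "n")
  log_bf0(batch$mean1, batch$mean2, batch$var1, batch$var2,
          n, n, attr(batch, "model"), hypothesis, fraction)
}
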