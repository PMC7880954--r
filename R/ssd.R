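#' Configuration for Bayesian sample-size determination
#'
#' Bundles everything the Monte-Carlo sample-size search needs: the
#' alternative population (the null population reuses its variances with
#' both means set to the second group's mean), the evidence threshold the
#' Bayes factor must exceed, the required probability `eta` of exceeding it
#' under each true population, the hypothesis pair, the number of simulated
#' datasets per population, the prior fractions for the sensitivity
#' analysis, and the seed.
#'
#' `eta` plays the role of one minus an error rate: the design requires
#' \eqn{P(BF_{0i} > \mathrm{thresh} \mid H_0) \ge \eta} and
#' \eqn{P(BF_{i0} > \mathrm{thresh} \mid H_i) \ge \eta}. Values of `eta` at
#' or below 0.5 are refused — such a design demands less than a coin flip.
#' Thresholds below 1 are accepted with a warning (threshold 1 itself is the
#' standard "which hypothesis is ahead" choice).
#'
#' @param pop A [population_spec()] for the alternative population. For a
#'   one-sided design the alternative must have \eqn{\mu_1 > \mu_2}, the
#'   orientation of the directional hypothesis.
#' @param bf_thresh Positive Bayes-factor threshold (e.g. 1, 3, 5, 10).
#' @param eta Required exceedance probability, in (0.5, 1).
#' @param hypothesis `"two-sided"` or `"one-sided"`.
#' @param n_datasets Simulated datasets per population per candidate sample
#'   size (default 10000; values below 10000 trigger a warning since the
#'   Monte-Carlo error on the probabilities is then non-negligible).
#' @param fractions Subset of `1:3`, the prior-fraction multipliers to
#'   report.
#' @param seed Integer master seed; all simulation streams derive from it.
#' @param n_start,n_max Search range for the per-group sample size.
#' @return An object of class `"ssd_config"`.
#' @export
#' @examples
#' ssd_config(population_spec(c(0.5, 0)), bf_thresh = 3, eta = 0.80)
ssd_config <- function(pop = population_spec(),
                       bf_thresh = 3, eta = 0.80,
                       hypothesis = c("two-sided", "one-sided"),
                       n_datasets = 10000, fractions = 1:3,
                       seed = 1L, n_start = 10L, n_max = 10000L) {
  stopifnot(inherits(pop, "population_spec"))
  hypothesis <- match.arg(hypothesis)
  if (!is.finite(bf_thresh) || bf_thresh <= 0)
    stop("bf_thresh must be a positive number", call. = FALSE)
  if (bf_thresh < 1)
    warning("bf_thresh < 1 requires less evidence than indifference",
            call. = FALSE)
  if (!is.finite(eta) || eta <= 0.5 || eta >= 1)
    stop("eta must lie in (0.5, 1)", call. = FALSE)
  if (!is.finite(n_datasets) || n_datasets < 1)
    stop("n_datasets must be a positive integer", call. = FALSE)
  if (n_datasets < 10000)
    warning("n_datasets below 10000; Monte-Carlo error on the exceedance ",
            "probabilities may be substantial", call. = FALSE)
  if (!all(fractions %in% 1:3) || length(fractions) < 1)
    stop("fractions must be a non-empty subset of 1:3", call. = FALSE)
  if (hypothesis == "one-sided" && pop$mu1 <= pop$mu2)
    stop("one-sided designs require mu1 > mu2 in the alternative population",
         call. = FALSE)
  if (n_start < 2 || n_max < n_start)
    stop("need 2 <= n_start <= n_max", call. = FALSE)
  structure(
    list(pop = pop, bf_thresh = bf_thresh, eta = eta,
         hypothesis = hypothesis, n_datasets = as.integer(n_datasets),
         fractions = as.integer(sort(unique(fractions))),
         seed = as.integer(seed),
         n_start = as.integer(n_start), n_max = as.integer(n_max)),
    class = "ssd_config"
  )
}

null_population <- function(pop) {
  population_spec(c(pop$mu2, pop$mu2), c(pop$sigma2_1, pop$sigma2_2),
                  pop$model)
}

#' Exceedance probabilities of the Bayes factor at a given sample size
#'
#' Simulates `n_datasets` datasets of per-group size `n` under the null
#' population (both means equal, variances as configured) and under the
#' alternative population, computes the Bayes factor for each on the
#' sufficient-statistic path, and returns the two empirical exceedance
#' proportions. Simulation streams are keyed by (seed, n, population), so
#' repeated calls — and calls with different `fraction` — reuse identical
#' datasets.
#'
#' @param n Per-group sample size.
#' @param config An [ssd_config()].
#' @param fraction Prior-fraction multiplier.
#' @return Named numeric vector: `p_null` = P(BF for H0 exceeds the
#'   threshold when H0 is true), `p_alt` = P(BF for the alternative exceeds
#'   the threshold when the alternative is true). The Monte-Carlo standard
#'   error of each is about \eqn{\sqrt{p(1-p)/n_\mathrm{datasets}}}.
#' @export
prob_exceed <- function(n, config, fraction = 1) {
  stopifnot(inherits(config, "ssd_config"))
  fraction <- check_fraction(fraction, n)
  lt <- log(config$bf_thresh)
  batch0 <- sim_suffstats(null_population(config$pop), n, config$n_datasets,
                          seed = child_seed(config$seed, n, 0L))
  batch1 <- sim_suffstats(config$pop, n, config$n_datasets,
                          seed = child_seed(config$seed, n, 1L))
  c(p_null = mean(log_bf0_batch(batch0, config$hypothesis, fraction) > lt),
    p_alt = mean(-log_bf0_batch(batch1, config$hypothesis, fraction) > lt))
}

#' Smallest sample size meeting the Bayes-factor design criterion
#'
#' Searches for the smallest per-group `n` at which [prob_exceed()] reaches
#' `eta` — for both populations by default, or for one of them alone via
#' `criterion` (the two-constraint answer is the maximum of the two
#' single-constraint answers, since each exceedance probability is monotone
#' in `n`). The search evaluates `n_start`, doubles until the criterion
#' passes, then bisects the bracket, treating the seed-matched empirical
#' probabilities as monotone in `n`; this keeps the number of Monte-Carlo
#' evaluations near a dozen even for sample sizes in the hundreds.
#'
#' @param config An [ssd_config()].
#' @param fraction Prior-fraction multiplier.
#' @param criterion Which constraint(s) must hold: `"both"` (default),
#'   `"null"` or `"alternative"`.
#' @return A list with the minimal `n`, the exceedance probabilities
#'   `p_null` and `p_alt` at that `n`, the number of Monte-Carlo
#'   `evaluations`, the `visited` sample sizes, and the Monte-Carlo standard
#'   errors `se_null`, `se_alt`.
#' @export
find_n <- function(config, fraction = 1,
                   criterion = c("both", "null", "alternative")) {
  stopifnot(inherits(config, "ssd_config"))
  criterion <- match.arg(criterion)
  meets <- function(p) switch(criterion,
    both = all(p >= config$eta),
    null = p[["p_null"]] >= config$eta,
    alternative = p[["p_alt"]] >= config$eta)

  visited <- integer(0)
  probe <- function(n) {
    visited[[length(visited) + 1L]] <<- as.integer(n)
    prob_exceed(n, config, fraction)
  }

  n <- config$n_start
  p <- probe(n)
  if (!meets(p)) {
    lo <- n  # largest failing n
    repeat {
      n <- min(2L * lo, config$n_max)
      p <- probe(n)
      if (meets(p)) break
      if (n >= config$n_max)
        stop(sprintf(paste0("criterion not met at n_max = %d ",
                            "(p_null = %.3f, p_alt = %.3f)"),
                     config$n_max, p[["p_null"]], p[["p_alt"]]),
             call. = FALSE)
      lo <- n
    }
    hi <- n
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (meets(probe(mid))) hi <- mid else lo <- mid
    }
    n <- hi
    p <- prob_exceed(n, config, fraction)  # stream is cached-by-seed: cheap
  }
  td <- config$n_datasets
  list(n = as.integer(n), p_null = p[["p_null"]], p_alt = p[["p_alt"]],
       evaluations = length(visited), visited = visited,
       se_null = sqrt(p[["p_null"]] * (1 - p[["p_null"]]) / td),
       se_alt = sqrt(p[["p_alt"]] * (1 - p[["p_alt"]]) / td),
       fraction = fraction, criterion = criterion)
}

#' Bayesian sample-size determination with prior-fraction sensitivity
#'
#' Runs [find_n()] for every prior fraction in the configuration. All
#' fractions are evaluated on identical simulated datasets (the streams are
#' keyed by sample size and population only), so differences between the
#' b/2b/3b sample sizes reflect the prior alone, not Monte-Carlo noise. The
#' recommended design is the maximum sample size across fractions: it
#' satisfies the criterion under every fraction considered.
#'
#' @param config An [ssd_config()].
#' @return An object of class `"ssd_result"`: per fraction the [find_n()]
#'   output, plus `recommendation` (max n across fractions) and the
#'   `config`.
#' @export
#' @examples
#' \donttest{
#' cfg <- ssd_config(population_spec(c(0.5, 0)), seed = 1, fractions = 1)
#' ssd_bayes(cfg)
#' }
ssd_bayes <- function(config) {
  stopifnot(inherits(config, "ssd_config"))
  per <- lapply(config$fractions, function(m) find_n(config, m))
  names(per) <- as.character(config$fractions)
  structure(
    list(fractions = per,
         recommendation = max(vapply(per, `[[`, integer(1), "n")),
         config = config),
    class = "ssd_result"
  )
}

#' Render a sample-size report
#'
#' Formats an [ssd_bayes()] result as the conventional per-fraction text
#' block, probabilities rounded to two decimals.
#'
#' @param result An `"ssd_result"`.
#' @return A character vector of report lines (invisibly printed by the
#'   print method).
#' @export
render_report <- function(result) {
  stopifnot(inherits(result, "ssd_result"))
  cfg <- result$config
  i <- if (cfg$hypothesis == "two-sided") "1" else "2"
  th <- format(cfg$bf_thresh, digits = 7)
  lines <- character(0)
  for (m in names(result$fractions)) {
    r <- result$fractions[[m]]
    frac <- if (m == "1") "b" else paste0(m, "b")
    lines <- c(
      lines,
      sprintf("Using N=%d and %s", r$n, frac),
      sprintf("P(BF0%s>%s|H0)=%.2f", i, th, r$p_null),
      sprintf("P(BF%s0>%s|H%s)=%.2f", i, th, i, r$p_alt)
    )
  }
  if (length(result$fractions) > 1L)
    lines <- c(lines, sprintf(
      "Sensitivity recommendation: N=%d per group (max over fractions)",
      result$recommendation))
  lines
}

#' @export
print.ssd_result <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}

#' Serialize a sample-size result as JSON
#'
#' Full-precision machine-readable counterpart of [render_report()]:
#' fraction multiplier mapped to n, both exceedance probabilities and the
#' number of search evaluations.
#'
#' @param result An `"ssd_result"`.
#' @return A JSON string.
#' @export
ssd_json <- function(result) {
  stopifnot(inherits(result, "ssd_result"))
  per <- lapply(result$fractions, function(r)
    list(N = r$n, p_null = r$p_null, p_alt = r$p_alt,
         evaluations = r$evaluations))
  jsonlite::toJSON(
    list(fractions = per, recommendation = result$recommendation,
         seed = result$config$seed, n_datasets = result$config$n_datasets),
    auto_unbox = TRUE, digits = NA
  )
}
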