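# Random small two-group summaries for property-style tests. When z is
# given, the standardized mean difference (mean1 - mean2 over the posterior
# sd of delta) is pinned to it, which keeps the posterior density at zero
# estimable for the kernel-density oracle.
random_summary <- function(model = c("equal", "unequal"), z = NULL) {
  model <- match.arg(model)
  n1 <- sample(5:80, 1)
  n2 <- if (model == "equal") sample(5:80, 1) else n1
  v <- stats::runif(2, 0.3, 3)
  if (model == "equal" && stats::runif(1) < 0.5) v[2] <- v[1]
  s <- two_group_summary(n1, n2,
                         mean1 = stats::rnorm(1, 0, 1.5),
                         mean2 = stats::rnorm(1, 0, 1.5),
                         var1 = v[1], var2 = v[2], model = model)
  if (!is.null(z)) {
    sd_delta <- sqrt(posterior_delta(s)$variance)
    s <- two_group_summary(n1, n2, s$mean1, s$mean1 - z * sd_delta,
                           v[1], v[2], model = model)
  }
  s
}

# Brute-force fit/complexity of a summary via draws from the explicit
# bivariate posterior/prior on (mu1, mu2) — the independent oracle for the
# analytic 1-D reduction to delta = mu1 - mu2.
brute_force_fc <- function(stats, fraction = 1, n_draws = 1e5) {
  if (stats$model == "equal") {
    s1 <- s2 <- pooled_variance(stats)
  } else {
    s1 <- stats$var1; s2 <- stats$var2
  }
  post1 <- rnorm(n_draws, stats$mean1, sqrt(s1 / stats$n1))
  post2 <- rnorm(n_draws, stats$mean2, sqrt(s2 / stats$n2))
  pri1 <- rnorm(n_draws, 0, sqrt(2 * s1 / fraction))
  pri2 <- rnorm(n_draws, 0, sqrt(2 * s2 / fraction))
  dens <- stats::density(post1 - post2)
  list(
    f0 = stats::approx(dens$x, dens$y, xout = 0)$y,
    f2 = mean(post1 > post2),
    c2 = mean(pri1 > pri2),
    n_draws = n_draws
  )
}

# Log BF01 through the raw-data route for a whole batch of simulated
# datasets (used for the raw vs sufficient-statistic equivalence checks).
log_bf_raw_batch <- function(pop, n, n_datasets, seed) {
  set.seed(seed)
  vapply(seq_len(n_datasets), function(i) {
    d <- sim_raw(pop, n)
    aafbf_raw(d$group1, d$group2, model = pop$model)$log_bf_0alt
  }, numeric(1))
}
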