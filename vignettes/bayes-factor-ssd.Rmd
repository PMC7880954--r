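---
title: "Methods: the fractional Bayes factor and Monte-Carlo sample-size determination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the fractional Bayes factor and Monte-Carlo sample-size determination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssdbf)
```

## The model

Observations in group $j \in \{1, 2\}$ are modelled as i.i.d.
$N(\mu_j, \sigma_j^2)$, with either a common within-group variance
(`model = "equal"`, the t-test setting) or group-specific variances
(`model = "unequal"`, the Welch setting). Three hypotheses about the means
are in play: $H_0: \mu_1 = \mu_2$, the two-sided alternative
$H_1: \mu_1 \neq \mu_2$, and the directional alternative
$H_2: \mu_1 > \mu_2$.

Each constrained hypothesis is scored against the unconstrained
alternative by fit over complexity,
$\mathrm{BF}_{i1} = f_i / c_i$: the fit $f_i$ is the posterior
density/mass of the constraint region, the complexity $c_i$ the same
quantity under the prior. The two-sided comparison uses $f_1 = c_1 = 1$
(the unconstrained fit and complexity integrate to one), so
$\mathrm{BF}_{01}$ is a pure Savage–Dickey density ratio; the directional
comparison composes as $\mathrm{BF}_{02} = \mathrm{BF}_{01} /
\mathrm{BF}_{21}$ with $\mathrm{BF}_{21} = f_2 / c_2$.

The posterior of $(\mu_1, \mu_2)$ is approximated by a bivariate normal
with the observed means as location and $\hat\sigma_j^2 / n_j$ on the
diagonal (pooled $\hat\sigma^2$ under the equal-variance model). The prior
is a zero-centred bivariate normal whose per-mean variance
$\hat\sigma_j^2 / (b_j\, n_j)$ is calibrated by a fraction
$b_j = m / (2 n_j)$ of the information in the data. Centring the prior on
the boundary $\mu_1 = \mu_2$ is what makes the equality constraint's
Savage–Dickey evaluation a default test that needs no subjective input.

**Reduction to one dimension.** Both distributions have diagonal
covariance, so the difference $\delta = \mu_1 - \mu_2$ is again normal:

* posterior: $\delta \sim N(\bar y_1 - \bar y_2,\;
  \hat\sigma^2 (1/n_1 + 1/n_2))$ or
  $N(\bar y_1 - \bar y_2,\; \hat\sigma_1^2/n_1 + \hat\sigma_2^2/n_2)$;
* prior: $\delta \sim N(0,\; 2(\hat\sigma_1^2 + \hat\sigma_2^2)/m)$,
  i.e. $N(0, 4\hat\sigma^2/m)$ with a pooled variance.

$f_0$ and $c_0$ are the two densities at $\delta = 0$; $f_2$ is the
posterior probability of $\delta > 0$ and $c_2 = 1/2$ exactly, for any
zero-mean prior — an inequality constraint's complexity does not depend on
the prior scale, hence not on the fraction. The reduction is exact given
the normal approximation, and replaces 2-D integration by closed forms.
The test suite cross-checks it against brute-force draws from the explicit
bivariate posterior and prior (55 random instances, $10^5$ draws each).

Two consequences worth knowing when reading output: multiplying the
fraction by $m$ multiplies $c_0$ by $\sqrt{m}$ and so divides
$\mathrm{BF}_{01}$ (and $\mathrm{BF}_{02}$) by $\sqrt{m}$ exactly; and the
Bayes factor is invariant to shifting all observations by a constant or
rescaling them by a common positive factor.

## Tunable parameters

* `bf_thresh` (dimensionless, default 3): the evidence level the design
  must reach. 1 means "which hypothesis is ahead"; 3/5/10 demand
  increasingly compelling support. Values below 1 are accepted with a
  warning — they demand less than indifference.
* `eta` (probability, default 0.80): required probability that the Bayes
  factor exceeds the threshold under each true population; $1 - \eta$ is
  the Bayesian counterpart of an error rate. Values at or below 0.5 are
  refused.
* `fraction` (multiplier $m \in \{1,2,3\}$ of $b = 1/(2n)$, default all
  three): $m = 1$ is the minimal-training-sample choice — half an
  observation per group, one in total, enough to identify the single
  contrast $\delta$; $m = 2$ (one case per mean) and $m = 3$ (plus half
  for the residual variance) are the conventional sensitivity variants.
* `n_datasets` (`T`, default 10,000): Monte-Carlo datasets per population
  per candidate $n$. The standard error of each exceedance probability is
  $\sqrt{p(1-p)/T} \approx 0.004$ at the default, so returned sample
  sizes can differ by a few units between seeds; values below 10,000
  trigger a warning.
* `n_start` / `n_max` (default 10 / 10,000): search range for the
  per-group sample size.

## What the generator emulates — and what it does not

`sim_suffstats()` draws datasets directly on the sufficient-statistic
scale: $\bar y_j \sim N(\mu_j, \sigma_j^2/n)$ and $s_j^2 \sim \sigma_j^2
\chi^2_{n-1}/(n-1)$, independently. For normal populations this *is* the
joint sampling distribution of the statistics the Bayes factor depends on,
so the fast path is statistically exact, not an approximation; the suite
confirms exchangeability with the raw-data route by a Kolmogorov–Smirnov
test on $10^4$ Bayes factors per route. The generator emulates exactly the
stated study conditions: independent normal groups of equal size, fixed
(not estimated) population means and variances. It does not emulate
non-normal or dependent data, unequal group sizes, measurement error in
the design inputs, or sequential data collection — so passing tests say
nothing about the method's robustness in those regimes, only that the
procedure is correct under its own assumptions.

The null population used by the search keeps the configured variances and
sets both means to the second group's mean; under a one-sided design the
alternative population must have $\mu_1 > \mu_2$, the orientation of
$H_2$, and the configuration refuses anything else.

## The search

`find_n()` evaluates the two exceedance probabilities at `n_start`,
doubles $n$ until both constraints pass (or `n_max` is reached, which is
an explicit error reporting the probabilities attained), then bisects the
bracket, treating the seed-matched empirical probabilities as monotone in
$n$. A search for $n \approx 100$ costs about a dozen Monte-Carlo
evaluations; $n \approx 700$ costs about seventeen. Each evaluation is
vectorized over the $2T$ datasets, so a full search takes well under a
second. The two-constraint answer equals the larger of the two
single-constraint answers (up to Monte-Carlo noise at the boundary), which
`criterion = "null"` / `"alternative"` exposes directly.

**Seeding.** Streams are keyed by (master seed, candidate $n$,
population). Different candidate $n$ necessarily use different datasets
(the datasets have different sizes), but re-evaluations at the same $n$
reuse identical data, and — deliberately — all prior fractions are
evaluated on the *same* datasets, so the b/2b/3b sensitivity triple
differs only through the prior, not through simulation noise. The
recommended design is the maximum $n$ across fractions: it satisfies the
criterion under every fraction considered.

## Numerical choices

* All Bayes-factor arithmetic is on the log scale, and one-sided fits use
  the log-CDF of the standard normal: at large $n$ the posterior density
  at zero and the tail mass underflow long before the Bayes factor itself
  is extreme (|z| beyond 8 is routine at $n$ in the hundreds).
* Variance estimates are unbiased (divisor $n - 1$); the pooled variance
  uses divisor $n_1 + n_2 - 2$.
* Unequal group sizes (Bayes factor only; the search itself uses equal
  per-group $n$): the posterior uses $\hat\sigma_j^2/n_j$ per group and
  the fraction is applied per group, $b_j = m/(2n_j)$, giving per-mean
  prior variance $2\hat\sigma_j^2/m$ — the natural per-group reading of
  the minimal-training-sample idea.
* Degenerate inputs fail loudly: fewer than two observations or zero
  variance in a group, non-positive thresholds, $\eta \notin (0.5, 1)$.
* Bisection treats the empirical pass/fail as monotone in $n$; at the
  boundary the Monte-Carlo noise can therefore move the returned $n$ by a
  few units between seeds. This is a property of the estimand (the
  boundary is genuinely flat to within the simulation error), not of the
  search.

## Classical baseline

`power_ttest()` / `ssd_freq()` provide the Neyman–Pearson counterpart:
exact power from the noncentral t distribution with $2n - 2$ degrees of
freedom and noncentrality $d\sqrt{n/2}$, and the exactly minimal $n$
reaching a target power. These reproduce the textbook per-group sizes 394,
64 and 26 for $d$ = 0.2, 0.5, 0.8 at $\alpha = .05$, two-sided, power .80,
and give a familiar anchor for comparing Bayesian and classical designs.

## Problem sizes used by the tests

The acceptance-level checks run the search at the full $T = 10{,}000$
datasets per population. Distributional and property checks use smaller
batches chosen for statistical resolution: $10^4$ Bayes factors per route
for the raw-vs-sufficient-statistic equivalence, $10^5$ draws per instance
for the 2-D oracle, $2{,}000$–$4{,}000$ datasets for monotonicity and
median checks. Counting oracles are compared at three Monte-Carlo standard
errors (plus a small discreteness cushion), density oracles at 5%.

## Known limitations

* The normal approximation of the posterior is an approximation at small
  $n$; the package makes no small-sample correction.
* Only two-group mean comparisons are covered — no ANOVA-style multi-group
  hypotheses, order-constrained composite hypotheses, or other Bayes
  factors (e.g. the Jeffreys–Zellner–Siow default-Cauchy family).
* The search assumes the exceedance probabilities are monotone in $n$,
  which holds for these designs but is enforced, not verified, per run.
* Simulation covers equal per-group sizes only; the unequal-$n$ Bayes
  factor generalization is available for data analysis but not optimized
  over in the design search.
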