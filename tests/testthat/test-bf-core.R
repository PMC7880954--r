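test_that("posterior of the mean difference matches the closed form", {
  s <- two_group_summary(100, 100, 0, 0, 1, 1)
  post <- posterior_delta(s)
  expect_equal(post$mean, 0)
  expect_equal(post$variance, 0.02)

  su <- two_group_summary(100, 100, 0, 0, 4 / 3, 2 / 3, "unequal")
  expect_equal(posterior_delta(su)$variance, 0.02)

  s2 <- two_group_summary(30, 50, 0.5, 0, 1.2, 0.8)
  expect_equal(posterior_delta(s2)$mean, 0.5)
  sp <- pooled_variance(s2)
  expect_equal(posterior_delta(s2)$variance, sp / 30 + sp / 50)
})

test_that("fractional prior is zero-centred with variance 4*s2/m", {
  s <- two_group_summary(100, 100, 0, 0, 1, 1)
  pr <- prior_delta(s, 1)
  expect_equal(pr$mean, 0)
  expect_equal(pr$variance, 4)
  expect_equal(complexity_equality(pr), 1 / sqrt(8 * pi))
  expect_equal(prior_delta(s, 2)$variance, 2)
  expect_equal(prior_delta(s, 3)$variance, 4 / 3)

  # zero-centred whatever the observed means
  for (i in 1:5) {
    set.seed(i)
    expect_equal(prior_delta(random_summary())$mean, 0)
  }
  su <- two_group_summary(40, 40, 1, 0, 4 / 3, 2 / 3, "unequal")
  expect_equal(prior_delta(su, 2)$variance, (4 / 3 + 2 / 3))
  expect_error(prior_delta(s, 1.5), "integer")
})

test_that("fit and complexity are normal densities and tail masses", {
  expect_equal(fit_equality(delta_dist(0, 0.02)), 1 / sqrt(2 * pi * 0.02))
  expect_equal(fit_equality(delta_dist(0.5, 0.02)),
               exp(-6.25) / sqrt(2 * pi * 0.02))
  expect_lt(fit_equality(delta_dist(0, 1e8)), 1e-3)

  expect_equal(fit_onesided(delta_dist(0, 0.02)), 0.5)
  expect_equal(fit_onesided(delta_dist(0.5, 0.02)),
               pnorm(0.5 / sqrt(0.02)))
  expect_gt(fit_onesided(delta_dist(0.5, 0.02)), 0.999)
  expect_equal(fit_onesided(delta_dist(-0.3, 0.1)),
               1 - fit_onesided(delta_dist(0.3, 0.1)))

  expect_identical(complexity_onesided(delta_dist(0, 4)), 0.5)
  expect_identical(complexity_onesided(delta_dist(0, 1e6)), 0.5)
  expect_error(complexity_onesided(delta_dist(0.2, 1)), "zero-mean")
})

test_that("Bayes factors invert, compose, and scale with the fraction", {
  for (i in 1:20) {
    set.seed(100 + i)
    s <- random_summary(sample(c("equal", "unequal"), 1))
    for (hyp in c("two-sided", "one-sided")) {
      b1 <- aafbf(s, hyp, 1)
      expect_equal(b1$bf_0alt * b1$bf_alt0, 1, tolerance = 1e-12)
      # fit/complexity recompose the BF
      bf21 <- b1$fit_alt / b1$complexity_alt
      expect_equal(b1$bf_0alt, (b1$fit_0 / b1$complexity_0) / bf21,
                   tolerance = 1e-12)
      for (m in 2:3) {
        bm <- aafbf(s, hyp, m)
        expect_equal(bm$complexity_0, b1$complexity_0 * sqrt(m),
                     tolerance = 1e-12)
        expect_equal(bm$bf_0alt, b1$bf_0alt / sqrt(m), tolerance = 1e-10)
      }
    }
  }
  # symmetric data: f2 = c2 = 0.5, so BF02 equals BF01
  s <- two_group_summary(50, 50, 1, 1, 0.8, 0.8)
  expect_equal(aafbf(s, "one-sided")$bf_0alt, aafbf(s, "two-sided")$bf_0alt)
})

test_that("one-sided complexity is 0.5 for any sample size and fraction", {
  for (n in c(5, 50, 5000)) {
    for (v in c(0.01, 1, 1e6)) {
      s <- two_group_summary(n, n, 0.3, -0.1, v, v)
      for (m in 1:3) {
        expect_identical(aafbf(s, "one-sided", m)$complexity_alt, 0.5)
      }
    }
  }
})

test_that("raw-data Bayes factor is location- and scale-invariant", {
  set.seed(21)
  g1 <- rnorm(40, 0.3, 1.1)
  g2 <- rnorm(40, 0, 0.9)
  for (model in c("equal", "unequal")) {
    for (hyp in c("two-sided", "one-sided")) {
      b <- aafbf_raw(g1, g2, model, hyp)
      shifted <- aafbf_raw(g1 + 100, g2 + 100, model, hyp)
      scaled <- aafbf_raw(3 * g1, 3 * g2, model, hyp)
      expect_equal(shifted$log_bf_0alt, b$log_bf_0alt, tolerance = 1e-9)
      expect_equal(scaled$log_bf_0alt, b$log_bf_0alt, tolerance = 1e-9)
      # f0 and c0 each scale by 1/k under y -> k*y
      expect_equal(scaled$fit_0, b$fit_0 / 3, tolerance = 1e-9)
      expect_equal(scaled$complexity_0, b$complexity_0 / 3,
                   tolerance = 1e-9)
    }
  }
})

test_that("equal and unequal variance models coincide for balanced data", {
  for (i in 1:10) {
    set.seed(200 + i)
    n <- sample(5:60, 1)
    v <- runif(1, 0.3, 3)
    s_eq <- two_group_summary(n, n, rnorm(1), rnorm(1), v, v, "equal")
    s_un <- two_group_summary(n, n, s_eq$mean1, s_eq$mean2, v, v, "unequal")
    for (hyp in c("two-sided", "one-sided"))
      expect_equal(aafbf(s_eq, hyp)$log_bf_0alt,
                   aafbf(s_un, hyp)$log_bf_0alt, tolerance = 1e-12)
  }
})

test_that("near-identical large samples favour the null", {
  set.seed(5)
  g <- rnorm(500)
  b <- aafbf_raw(g, g + rnorm(500, 0, 1e-3))
  expect_gt(b$bf_0alt, 1)
})

test_that("aafbf results serialize to the documented JSON keys", {
  s <- two_group_summary(100, 100, 0, 0, 1, 1)
  parsed <- jsonlite::fromJSON(aafbf_json(aafbf(s, "one-sided", 2)))
  expect_named(parsed, c("fit_0", "complexity_0", "fit_alt",
                         "complexity_alt", "bf_0alt", "bf_alt0",
                         "hypothesis", "fraction_multiplier"))
  expect_equal(parsed$fraction_multiplier, 2)
  expect_equal(parsed$complexity_alt, 0.5)
})
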