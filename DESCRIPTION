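Package: ssdbf
Title: Sample-Size Determination for Bayesian Two-Sample Tests with the
    Approximate Adjusted Fractional Bayes Factor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the approximate adjusted fractional Bayes factor
    (AAFBF) for the two-sample t test and Welch's test, comparing the null
    hypothesis of equal means against a two-sided or one-sided (directional)
    alternative, from raw observations or summary statistics. Provides a
    Monte-Carlo sample-size determination procedure that finds the smallest
    per-group sample size at which the Bayes factor exceeds a user-chosen
    evidence threshold with probability at least eta under both the null and
    the alternative population, together with a sensitivity analysis over the
    prior fraction (b, 2b, 3b). Also includes classical power and sample-size
    computations for the two-sample t test based on the noncentral t
    distribution, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
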