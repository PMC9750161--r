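Package: skewfa
Title: Factor Retention Methods for Skewed Ordinal Rating-Scale Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying overfactoring when linear factor models are
    fitted to skewed ordinal (Likert-type) data. Implements a one-factor
    categorical data generator with binomial-marginal thresholds targeting a
    prescribed skewness, two-step polychoric correlation estimation with an
    influence-based asymptotic covariance, maximum-likelihood exploratory
    factor analysis, diagonally weighted least squares (WLSMV) with
    Satorra-Bentler mean and mean-and-variance corrected test statistics and
    the scaled chi-square difference test, a marginal maximum-likelihood EM
    fitter for Samejima's graded response model, Horn-style parallel analysis
    on Pearson or polychoric correlations, and a Monte Carlo harness that
    summarises the empirical proportion of samples retaining the one-factor
    model (EPS), effect sizes for the logit p-value, and parameter-recovery
    error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
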