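Package: pebatest
Title: Penalized Eigenvalue Block Averaging Tests for Factor Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Robust goodness-of-fit and nested model comparison tests for
    confirmatory factor models under non-normality. Implements normal-theory
    maximum likelihood estimation for single- and multi-group factor models,
    the ML and reweighted least squares (RLS) chi-square statistics, and a
    family of eigenvalue-based p values that stabilize the weights of the
    limiting chi-square mixture: Satorra-Bentler mean scaling, eigenvalue
    block averaging (EBA), penalized block averaging (pEBA), a penalized
    regression smoother (pOLS2), the scaled-and-shifted test, and the scaled
    F test, each crossed with biased or unbiased estimation of the asymptotic
    covariance matrix of sample covariances. Extends the eigenvalue methods
    to nested multi-group comparisons (weak measurement invariance), with the
    difference weight matrix computed either from the unrestricted model
    alone or as a difference of per-model projections. Includes exact-moment
    non-normal data generators (Vale-Maurelli, independent generator,
    piecewise linear) and a Monte Carlo harness with the rejection-rate
    aggregation metrics used to evaluate such tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    numDeriv,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
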