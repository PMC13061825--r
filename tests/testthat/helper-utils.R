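# Shared helpers for the test suite.

sample_skew_kurt <- function(x) {
  xc <- x - mean(x)
  s2 <- mean(xc^2)
  c(skew = mean(xc^3) / s2^1.5, exkurt = mean(xc^4) / s2^2 - 3)
}

# One-free-parameter model: a single observed variable with free variance.
scalar_spec <- function() {
  pebatest:::new_cfa_spec(
    lambda_labels = list(matrix("", 1, 1)),
    lambda_fixed = list(matrix(0, 1, 1)),
    phi_labels = list(matrix("", 1, 1)),
    phi_fixed = list(matrix(1, 1, 1)),
    psi_labels = list(matrix("v", 1, 1)),
    psi_fixed = list(matrix(0, 1, 1))
  )
}

# One-factor spec with p indicators, standardized-factor identification.
one_factor_spec <- function(p) simple_cfa_spec(rep(1, p))

# Population sigma for a one-factor model with given loadings, unit factor
# and residual variances.
one_factor_sigma <- function(lambda) {
  tcrossprod(lambda) + diag(length(lambda))
}

expect_tibble_row <- function(x) {
  expect_s3_class(x, "tbl_df")
  expect_equal(nrow(x), 1L)
}
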