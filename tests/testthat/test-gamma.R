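test_that("plug-in Gamma matches hand-computed central moments", {
  # scalar data (-1, 0, 1): s = 2/3, m4 = 2/3, gamma = 2/3 - 4/9 = 2/9
  g <- gamma_adf(matrix(c(-1, 0, 1), 3, 1))
  expect_equal(as.numeric(g), 2 / 9)
  expect_error(gamma_adf(matrix(c(0, 1), 2, 1)), "at least 3")
})

test_that("a constant column yields zero rows and columns", {
  set.seed(1)
  X <- cbind(rnorm(50), 5)
  g <- unclass(gamma_adf(X))
  # vech index 2 = (2,1), 3 = (2,2) involve the constant column
  expect_equal(g[2:3, ], matrix(0, 2, 3))
  expect_equal(g[, 2:3], matrix(0, 3, 2))
})

test_that("Gamma estimators are invariant to observation order", {
  set.seed(2)
  X <- matrix(rexp(300), 100, 3)
  perm <- sample(100)
  expect_equal(unclass(gamma_adf(X)), unclass(gamma_adf(X[perm, ])))
  expect_equal(unclass(gamma_unbiased(X)), unclass(gamma_unbiased(X[perm, ])))
})

test_that("plug-in Gamma approaches the normal-theory value under normality", {
  set.seed(3)
  sigma <- matrix(c(1, 0.5, 0.5, 1), 2)
  n <- 50000
  X <- pebatest:::rnorm_chol(n, sigma)
  g <- unclass(gamma_adf(X))
  g0 <- gamma_normal_theory_pop(sigma)
  # entrywise 3 MC SEs: var of a fourth-moment average is of order
  # (8th moment)/n; bound all entries by a common generous constant
  expect_lt(max(abs(g - g0)), 3 * sqrt(100 / n))
})

test_that("the corrected estimator is unbiased where the plug-in is not", {
  # scalar centered exponential: sigma2 = 1, mu4 = 9 (by the integral
  # oracle below), so Gamma = mu4 - sigma^4 = 8
  mu4 <- stats::integrate(function(x) (x - 1)^4 * exp(-x), 0, Inf,
                          rel.tol = 1e-10)$value
  expect_equal(mu4, 9, tolerance = 1e-6)
  n <- 20
  reps <- 20000
  set.seed(4)
  vals_u <- numeric(reps)
  vals_b <- numeric(reps)
  for (r in seq_len(reps)) {
    x <- matrix(rexp(n) - 1, n, 1)
    vals_u[r] <- as.numeric(gamma_unbiased(x))
    vals_b[r] <- as.numeric(gamma_adf(x))
  }
  target <- mu4 - 1
  se_u <- sd(vals_u) / sqrt(reps)
  expect_lt(abs(mean(vals_u) - target), 3 * se_u)
  # the plug-in shows systematic negative bias at this sample size
  expect_lt(mean(vals_b) + 3 * sd(vals_b) / sqrt(reps), target)
})

test_that("biased and unbiased variants agree asymptotically", {
  set.seed(5)
  X <- matrix(rexp(2e5 * 2), ncol = 2)
  gb <- unclass(gamma_adf(X))
  gu <- unclass(gamma_unbiased(X))
  expect_lt(max(abs(gb - gu)), 1e-3 * norm(gb, "F"))
  expect_equal(dim(gb), c(3L, 3L))
  expect_equal(gb, t(gb))
})

test_that("joint multi-group Gamma is block diagonal with inverse weights", {
  set.seed(6)
  X1 <- matrix(rnorm(200), 100, 2)
  X2 <- matrix(rnorm(600), 300, 2)
  gj <- unclass(gamma_joint(list(X1, X2), "biased"))
  expect_equal(dim(gj), c(6L, 6L))
  expect_equal(gj[1:3, 4:6], matrix(0, 3, 3))
  expect_lt(max(abs(gj[1:3, 1:3] - unclass(gamma_adf(X1)) * 400 / 100)),
            1e-12)
  expect_lt(max(abs(gj[4:6, 4:6] - unclass(gamma_adf(X2)) * 400 / 300)),
            1e-12)
})
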