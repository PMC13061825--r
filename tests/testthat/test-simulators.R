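test_that("Fleishman coefficients solve the moment system", {
  expect_equal(fleishman_coefficients(0, 0), c(a = 0, b = 1, c = 0, d = 0))
  for (tg in list(c(2, 7), c(3, 21))) {
    cf <- fleishman_coefficients(tg[1], tg[2])
    b <- cf[["b"]]; cc <- cf[["c"]]; d <- cf[["d"]]
    expect_equal(b^2 + 6 * b * d + 2 * cc^2 + 15 * d^2, 1, tolerance = 1e-10)
    expect_equal(2 * cc * (b^2 + 24 * b * d + 105 * d^2 + 2), tg[1],
                 tolerance = 1e-10)
    expect_equal(24 * (b * d + cc^2 * (1 + b^2 + 28 * b * d) +
                         d^2 * (12 + 48 * b * d + 141 * cc^2 + 225 * d^2)),
                 tg[2], tolerance = 1e-9)
    expect_equal(cf[["a"]], -cf[["c"]])
  }
  expect_error(fleishman_coefficients(3, 2), "feasibility|inequality")
})

test_that("severe-target transform hits its moments in large samples", {
  cf <- fleishman_coefficients(3, 21)
  set.seed(1)
  n <- 1e6
  x <- pebatest:::fleishman_transform(rnorm(n), cf)
  sk <- sample_skew_kurt(x)
  # MC standard errors of skewness/kurtosis estimators under heavy tails are
  # large; use generous 3-SE style bounds calibrated by the batch spread
  batches <- matrix(x, ncol = 20)
  sks <- apply(batches, 2, sample_skew_kurt)
  expect_lt(abs(sk["skew"] - 3), 3 * sd(sks[1, ]) / sqrt(20) * sqrt(20))
  expect_lt(abs(sk["exkurt"] - 21), 3 * sd(sks[2, ]) / sqrt(20) * sqrt(20))
})

test_that("all generators reduce to the normal when targets vanish", {
  pop <- build_study_population("study2", 5, G = 1, seed = 5)
  sig <- pop$sigma[[1]]
  set.seed(2)
  for (fun in list(
    function(n) vm_sample(sig, 0, 0, n),
    function(n) pl_sample(sig, 0, 0, n),
    function(n) ig_sample(pop$lambda[[1]], diag(1), diag(pop$psi), 0, 0, n)
  )) {
    X <- fun(5e4)
    sk <- apply(X, 2, sample_skew_kurt)
    expect_lt(max(abs(sk[1, ])), 0.1)
    expect_lt(max(abs(sk[2, ])), 0.2)
    expect_lt(max(abs(pebatest:::sample_cov_biased(X) - sig)), 0.08)
  }
})

test_that("generators hit the target covariance and marginal moments", {
  pop <- build_study_population("study2", 5, G = 1, seed = 5)
  sig <- pop$sigma[[1]]
  n <- 4e5
  for (fam in c("VM1", "PL1", "IG1")) {
    X <- draw_sample(pop, fam, n, seed = 3)[[1]]
    sk <- apply(X, 2, sample_skew_kurt)
    # moderate targets (2, 7); tolerances from the asymptotic sd of the
    # estimators under the fitted tails (~sqrt(c/n) with c in the hundreds)
    expect_lt(max(abs(sk[1, ] - 2)), 0.12)
    expect_lt(max(abs(sk[2, ] - 7)), 1.0)
    dev <- abs(pebatest:::sample_cov_biased(X) - sig)
    expect_lt(max(dev), 0.05)
  }
})

test_that("moment deviations shrink with sample size", {
  pop <- build_study_population("study2", 5, G = 1, seed = 5)
  devs <- vapply(c(1e3, 1e4, 1e5), function(n) {
    X <- draw_sample(pop, "VM1", n, seed = 4)[[1]]
    sk <- apply(X, 2, sample_skew_kurt)
    mean(abs(sk[1, ] - 2))
  }, numeric(1))
  expect_lt(devs[3], devs[1])
})

test_that("sample skewness and kurtosis are biased down at n = 400", {
  pop <- build_study_population("study2", 5, G = 1, seed = 5)
  gen <- prepare_generator(pop, "VM2")
  set.seed(5)
  sk <- rowMeans(vapply(1:400, function(r) {
    rowMeans(apply(gen(400)[[1]], 2, sample_skew_kurt))
  }, numeric(2)))
  expect_lt(sk[1], 3)
  expect_lt(sk[2], 21)
})

test_that("identical seeds reproduce identical samples", {
  pop <- build_study_population("study2", 5, G = 2, seed = 5)
  for (fam in c("N", "VM1", "IG1", "PL1")) {
    X1 <- draw_sample(pop, fam, 100, seed = 42)
    X2 <- draw_sample(pop, fam, 100, seed = 42)
    expect_identical(X1, X2)
  }
})

test_that("same-moment families differ beyond the matched moments", {
  # VM1 and PL1 share covariance, skewness and kurtosis, yet are different
  # distributions: their standardized sixth marginal moments separate
  pop <- build_study_population("study2", 5, G = 1, seed = 5)
  n <- 4e5
  Xv <- draw_sample(pop, "VM1", n, seed = 6)[[1]]
  Xp <- draw_sample(pop, "PL1", n, seed = 7)[[1]]
  m6 <- function(x) {
    z <- (x - mean(x)) / sd(x)
    c(est = mean(z^6), se = sd(z^6) / sqrt(length(z)))
  }
  a <- m6(Xv[, 1])
  b <- m6(Xp[, 1])
  expect_gt(abs(a["est"] - b["est"]), 3 * (a["se"] + b["se"]))
})

test_that("study populations encode the design misspecifications", {
  pop3 <- build_study_population("study3_gof", 15, seed = 1)
  mv <- pop3$misspec$vector
  expect_equal(abs(mv[c(1, 3)]), c(0.78, 0.78))
  expect_equal(mv[1], -mv[2 + 1])  # alternating signs on odd indicators
  expect_equal(sum(mv != 0), 2L)   # odd indicators of factor 1 (p/5 = 3)
  expect_error(build_study_population("study3_gof", 100, seed = 1),
               "p = 15, 30, 60")

  pop2 <- build_study_population("study2", 5, G = 4, seed = 1)
  expect_equal(pop2$pair$m0$df, 32L)
  expect_equal(pop2$pair$m1$df, 20L)

  # invariance power population perturbs loadings only in groups 2..G
  popi <- build_study_population("study3_invariance", 5, G = 2, seed = 1,
                                 h = 0.2)
  expect_equal(popi$lambda[[2]][, 1] - popi$lambda[[1]][, 1],
               0.2 * (-1)^(1:5))
})

test_that("nested loading draws are consistent across dimensions", {
  p15 <- build_study_population("study1", 15, seed = 9)
  p30 <- build_study_population("study1", 30, seed = 9)
  lam15 <- p15$lambda[p15$lambda != 0]
  lam30 <- p30$lambda[p30$lambda != 0]
  # factor j's loadings at p = 15 are the first 3 of its p = 30 loadings
  for (j in 1:5) {
    expect_equal(lam15[(j - 1) * 3 + 1:3], lam30[(j - 1) * 6 + 1:3])
  }
})
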