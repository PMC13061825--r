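test_that("pEBA with one block is exactly Satorra-Bentler", {
  set.seed(1)
  for (rep in 1:5) {
    lam <- sort(rexp(7))
    t <- runif(1, 2, 25)
    p1 <- pvalue_eigen(t, lam, "pEBA", nblocks = 1)$p_value
    p2 <- pvalue_eigen(t, lam, "SB")$p_value
    expect_equal(p1, p2, tolerance = 1e-9)
    # SB equals the rescaled chi-square tail
    expect_equal(p2, pchisq(t / mean(lam), df = 7, lower.tail = FALSE),
                 tolerance = 1e-7)
  }
})

test_that("unit weights reduce every procedure to the naive chi-square", {
  lam <- rep(1, 12)
  t <- 15
  naive <- pchisq(t, 12, lower.tail = FALSE)
  expect_equal(pvalue_eigen(t, lam, "ALL")$p_value, naive, tolerance = 1e-7)
  ss <- pvalue_ss(t, lam)
  expect_equal(ss$statistic, t)          # a = 1, b = d -> T_SS = T
  expect_equal(ss$p_value, naive, tolerance = 1e-10)
  expect_equal(pvalue_sf(t, lam)$p_value, naive, tolerance = 1e-7)
})

test_that("the scaled-and-shifted statistic matches hand arithmetic", {
  # d = 2, tr = 4, tr2 = 10, T = 5:
  # a = sqrt(0.2), b = sqrt(3.2), T_SS = 2.4472, p = 0.2942
  lam <- c(1, 3)  # sums: 4 and 10
  res <- pvalue_ss(5, lam)
  expect_equal(res$statistic, sqrt(0.2) * 5 + 2 - sqrt(3.2),
               tolerance = 1e-6)
  expect_equal(res$p_value, exp(-res$statistic / 2), tolerance = 1e-10)
  expect_equal(res$p_value, 0.2942, tolerance = 3e-4)
})

test_that("the scaled F tail matches a Monte Carlo oracle", {
  # equal weights: reduces to the exact scaled chi-square
  lam <- rep(0.8, 6)
  t_alpha <- 0.8 * qchisq(0.95, 6)
  expect_equal(pvalue_sf(t_alpha, lam)$p_value, 0.05, tolerance = 1e-6)

  # heterogeneous weights: compare to simulation at the 5% tail
  set.seed(4)
  lam <- sort(rexp(10) + 0.2)
  draws <- 3e5
  q <- colSums(lam * matrix(rnorm(10 * draws)^2, 10, draws))
  t95 <- unname(quantile(q, 0.95))
  p_sf <- pvalue_sf(t95, lam)$p_value
  expect_gt(p_sf, 0.03)
  expect_lt(p_sf, 0.07)
  # monotone nonincreasing in the statistic
  ps <- vapply(seq(1, 50, length.out = 20),
               function(t) pvalue_sf(t, lam)$p_value, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("the full battery emits 38 labelled results", {
  pop <- build_study_population("study1", 15, seed = 3)
  set.seed(5)
  X <- draw_sample(pop, "N", 500)[[1]]
  fit <- fit_cfa(as.data.frame(X), pop$spec)
  res <- gof_tests(fit, X)
  expect_equal(nrow(res), 38L)
  expect_equal(sum(res$procedure %in% c("ML", "RLS")), 2L)
  expect_equal(sum(grepl("_UG$", res$procedure)), 18L)
  expect_equal(sum(grepl("_RLS", res$procedure)), 18L)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_true(all(res$statistic >= 0))
  # labels round-trip through the result writer
  path <- tempfile(fileext = ".tsv")
  write_results(res, path, metadata = list(seed = 5))
  back <- read_results(path)
  expect_equal(back$procedure, res$procedure)
  expect_equal(back$p_value, res$p_value)  # 17 digits: bit-faithful
  expect_equal(attr(back, "metadata")$seed, "5")
})

test_that("RLS-based eigenvalue procedures hold their size under normality", {
  # null rejection rates of every eigenvalue-based RLS procedure stay inside
  # the Bradley band, allowing 3 binomial SEs at this replication count
  cond <- list(study = "study1", p = 15, G = 1, n = 2000, family = "N",
               reps = 200, seed = 77)
  methods <- c("ALL_RLS", "pEBA2_RLS", "pEBA4_RLS", "pEBA6_RLS",
               "pEBAdf_RLS", "pOLS2_RLS", "SB_RLS")
  res <- run_condition(cond, methods = methods)
  slack <- 3 * sqrt(5 * 95 / 200)
  expect_true(all(res$rejection_rate >= max(0, 2.5 - slack) &
                    res$rejection_rate <= 7.5 + slack))
})

test_that("robustified p values approach the naive one at large n", {
  pop <- build_study_population("study1", 15, seed = 3)
  set.seed(6)
  X <- draw_sample(pop, "N", 50000)[[1]]
  fit <- fit_cfa(as.data.frame(X), pop$spec)
  res <- gof_tests(fit, X)
  naive <- res$p_value[res$procedure == "ML"]
  robust_ml <- res$p_value[res$base == "ML" & res$procedure != "ML"]
  expect_true(all(abs(robust_ml - naive) < 0.02))
})
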