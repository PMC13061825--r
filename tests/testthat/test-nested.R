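make_nested_fits <- function(p = 5, G = 2, n = 400, family = "N", seed = 13,
                             pop_seed = 4) {
  pop <- build_study_population("study2", p, G = G, seed = pop_seed)
  pair <- pop$pair
  set.seed(seed)
  Xl <- draw_sample(pop, family, n)
  Sl <- lapply(Xl, pebatest:::sample_cov_biased)
  Nl <- as.list(rep(n, G))
  fit1 <- pebatest:::fit_m1_groupwise(Sl, Nl, pair)
  fit0 <- fit_ntml(Sl, Nl, pair$m0,
                   start = pebatest:::m0_start_from_m1(fit1, pair))
  list(pop = pop, pair = pair, X = Xl, fit0 = fit0, fit1 = fit1)
}

test_that("the difference statistic is the plain difference", {
  env <- make_nested_fits()
  f0 <- env$fit0; f1 <- env$fit1
  expect_equal(t_diff(f0, f1, "ML"), t_ml(f0) - t_ml(f1))
  expect_equal(t_diff(f0, f1, "RLS"), t_rls(f0) - t_rls(f1))
  expect_error(t_diff(f1, f0, "ML"), "df0 > df1")
})

test_that("difference statistic has the chi-square limit mean under the null", {
  pop <- build_study_population("study2", 5, G = 2, seed = 4)
  pair <- pop$pair
  gen <- prepare_generator(pop, "N")
  set.seed(14)
  R <- 300
  td <- numeric(R)
  for (r in seq_len(R)) {
    Xl <- gen(2000)
    Sl <- lapply(Xl, pebatest:::sample_cov_biased)
    Nl <- list(2000, 2000)
    f1 <- pebatest:::fit_m1_groupwise(Sl, Nl, pair)
    f0 <- fit_ntml(Sl, Nl, pair$m0,
                   start = pebatest:::m0_start_from_m1(f1, pair))
    td[r] <- t_ml(f0) - t_ml(f1)
  }
  expect_lt(abs(mean(td) - 4), 3 * sd(td) / sqrt(R))
  # naive difference-test p values are approximately uniform under the null
  pvals <- pchisq(td, 4, lower.tail = FALSE)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.001)
})

test_that("the single-model U_D has the design eigenvalue structure", {
  for (cfg in list(c(5, 2), c(10, 4), c(20, 8))) {
    p <- cfg[1]; G <- cfg[2]
    pop <- build_study_population("study2", p, G = G, seed = 4)
    pair <- pop$pair
    fit1 <- fit_ntml(pop$sigma, as.list(rep(5000, G)), pair$m1)
    ud <- u_d_2000(fit1, pair$A)
    gnt <- pebatest:::block_diag(lapply(seq_len(G), function(g) {
      gamma_normal_theory_pop(fit1$sigma_hat[[g]]) * G
    }))
    w <- nested_eigen_weights(ud, gnt)
    expect_length(w, (G - 1) * (p - 1))
    # asymptotic robustness in the normal case: all weights are one
    expect_equal(w, rep(1, length(w)), tolerance = 1e-6)
  }
})

test_that("eigenvalue sum equals the trace for the single-model method", {
  env <- make_nested_fits(family = "VM1", seed = 15)
  ud <- u_d_2000(env$fit1, env$pair$A)
  gam <- gamma_joint(env$X, "biased")
  w <- nested_eigen_weights(ud, gam)
  tr <- sum(ud$K * crossprod(ud$X, unclass(gam) %*% ud$X))
  expect_equal(sum(w), tr, tolerance = 1e-8 * abs(tr))
})

test_that("the two U_D estimators agree at the population parameters", {
  pop <- build_study_population("study2", 5, G = 2, seed = 4)
  pair <- pop$pair
  Nl <- list(4000, 4000)
  fit1 <- fit_ntml(pop$sigma, Nl, pair$m1)
  fit0 <- fit_ntml(pop$sigma, Nl, pair$m0)
  ud0 <- u_d_2000(fit1, pair$A)
  ud1 <- u_d_2001(fit0, fit1)
  expect_lt(max(abs(pebatest:::ud_full(ud0) - ud1$U)), 1e-6)
})

test_that("the projection-difference method differs in finite samples", {
  env <- make_nested_fits(family = "VM1", seed = 16)
  ud1 <- u_d_2001(env$fit0, env$fit1)
  gam <- gamma_joint(env$X, "biased")
  w <- nested_eigen_weights(ud1, gam)
  tr <- sum(ud1$U * t(unclass(gam)))
  # trace and eigenvalue sum genuinely separate for the 2001 method
  expect_gt(abs(sum(w) - tr), 1e-6)
})

test_that("identical models give a zero difference weight matrix", {
  pop <- build_study_population("study2", 5, G = 2, seed = 4)
  pair <- pop$pair
  fit0 <- fit_ntml(pop$sigma, list(500, 500), pair$m1)
  ud <- u_d_2001(fit0, fit0)
  expect_equal(max(abs(ud$U)), 0, tolerance = 1e-8)
  expect_equal(ud$d, 0L)
})

test_that("trace-form Satorra-Bentler difference test matches hand values", {
  # c = tr / d = 8/4 = 2 -> p = P(chi2_4 > 5) = 0.2873
  ud <- structure(list(U = diag(2) * 4, d = 4, method = "2001"),
                  class = "u_d")
  res <- sb_2001_trace(10, ud, diag(2))
  expect_equal(res$statistic, 5)
  expect_equal(res$p_value, pchisq(5, 4, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(res$p_value, 0.2873, tolerance = 1e-4)
})

test_that("trace-form and eigenvalue-sum SB coincide under the 2000 method", {
  env <- make_nested_fits(family = "VM1", seed = 17)
  gam <- gamma_joint(env$X, "biased")
  ud <- u_d_2000(env$fit1, env$pair$A)
  td <- suppressWarnings(t_diff(env$fit0, env$fit1, "ML"))
  w <- nested_eigen_weights(ud, gam)
  p_eig <- pvalue_eigen(td, w, "SB")$p_value
  p_tr <- sb_2001_trace(td, ud, gam)$p_value
  expect_equal(p_eig, p_tr, tolerance = 1e-6)
})

test_that("nested battery emits the full method crossing plus SB_2001", {
  env <- make_nested_fits(seed = 18)
  res0 <- suppressWarnings(nested_tests(env$fit0, env$fit1, env$X,
                                        A = env$pair$A, ud_method = "2000"))
  # d0 - d1 = 4 < 6 blocks: pEBA6 is skipped with a warning, leaving 32
  expect_equal(nrow(res0), 32L)
  res1 <- suppressWarnings(nested_tests(env$fit0, env$fit1, env$X,
                                        A = env$pair$A, ud_method = "2001"))
  expect_equal(nrow(res1), 33L)
  expect_true("SB_2001" %in% res1$procedure)
  expect_true(all(res0$p_value >= 0 & res0$p_value <= 1))
  # unit-weight reduction: with all weights 1 the SB p value is the naive one
  td <- suppressWarnings(t_diff(env$fit0, env$fit1, "ML"))
  expect_equal(pvalue_eigen(td, rep(1, 4), "SB")$p_value,
               pchisq(td, 4, lower.tail = FALSE), tolerance = 1e-8)
})

test_that("the data-frame invariance interface runs end to end", {
  pop <- build_study_population("study2", 5, G = 2, seed = 4)
  set.seed(19)
  Xl <- draw_sample(pop, "N", 300)
  df <- as.data.frame(do.call(rbind, Xl))
  names(df) <- paste0("x", 1:5)
  df$group <- rep(1:2, each = 300)
  out <- suppressWarnings(weak_invariance_tests(df, "group"))
  expect_true(all(c("fit0", "fit1", "tests") %in% names(out)))
  expect_equal(out$fit0$df - out$fit1$df, 4L)
  expect_true("pEBAdf_UG" %in% out$tests$procedure)
})
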