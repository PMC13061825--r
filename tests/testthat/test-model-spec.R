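test_that("model degrees of freedom match the design tables", {
  s15 <- study_gof_spec(15)
  expect_equal(s15$q, 40L)
  expect_equal(model_degrees_of_freedom(s15), 80L)
  expect_equal(study_gof_spec(30)$q, 70L)
  expect_equal(study_gof_spec(60)$q, 130L)
  s100 <- study_gof_spec(100)
  expect_equal(s100$q, 210L)
  expect_equal(model_degrees_of_freedom(s100), 4840L)
})

test_that("saturated and under-identified specs are handled", {
  # p = 1 with one free variance: saturated, d = 0
  expect_equal(model_degrees_of_freedom(scalar_spec()), 0L)
  expect_error(simple_cfa_spec(c(1, 1)), "under-identified")
})

test_that("invariance pairs reproduce the design degrees of freedom", {
  # (p, G, df0, df1) rows of the invariance design table
  rows <- list(
    c(5, 2, 14, 10), c(5, 4, 32, 20), c(5, 8, 68, 40),
    c(10, 2, 79, 70), c(10, 4, 167, 140), c(10, 8, 343, 280),
    c(20, 2, 359, 340), c(20, 4, 737, 680), c(20, 8, 1493, 1360)
  )
  for (r in rows) {
    pair <- make_invariance_pair(r[1], r[2])
    expect_equal(pair$m0$df, r[3])
    expect_equal(pair$m1$df, r[4])
    q <- pair$m0$df - pair$m1$df
    expect_equal(q, (r[2] - 1) * (r[1] - 1))
    expect_equal(nrow(pair$A), q)
    expect_equal(qr(pair$A)$rank, q)
  }
})

test_that("degenerate invariance pairs follow the caller flag", {
  expect_error(make_invariance_pair(5, 1), "G >= 2")
  pair <- make_invariance_pair(5, 1, allow_single_group = TRUE)
  expect_equal(pair$m0$df, pair$m1$df)
  expect_equal(nrow(pair$A), 0L)
  expect_error(make_invariance_pair(2, 2), "p >= 3")
})

test_that("build_sigma evaluates the factor decomposition", {
  sp <- one_factor_spec(3)
  # loadings 0.5, unit factor and residual variances
  th <- c(rep(0.5, 3), rep(1, 3))
  sig <- build_sigma(th, sp)
  expect_equal(diag(sig), rep(1.25, 3))
  expect_equal(sig[lower.tri(sig)], rep(0.25, 3))
  # zero loadings, identity residuals
  expect_equal(build_sigma(c(0, 0, 0, 1, 1, 1), sp), diag(3))
  expect_error(build_sigma(c(1, 2), sp), "length")
})

test_that("theta round-trips through the matrix views", {
  pair <- make_invariance_pair(5, 3)
  set.seed(2)
  th <- runif(pair$m0$q, 0.5, 1.5)
  mats <- lapply(1:3, function(g) pebatest:::theta_matrices(th, pair$m0, g))
  expect_equal(pebatest:::matrices_to_theta(mats, pair$m0), th)
  # constrained loadings identical across groups
  expect_equal(mats[[1]]$lambda, mats[[2]]$lambda)
})

test_that("analytic moment Jacobian matches finite differences", {
  skip_if_not_installed("numDeriv")
  set.seed(3)
  specs <- list(study_gof_spec(15), make_invariance_pair(5, 2)$m0,
                make_invariance_pair(5, 2)$m1)
  for (sp in specs) {
    th <- runif(sp$q, 0.4, 1.3)
    D <- delta_jacobian(th, sp)
    fd <- numDeriv::jacobian(function(t) {
      unlist(lapply(seq_len(sp$G), function(g) vech(build_sigma(t, sp, g))))
    }, th)
    expect_lt(max(abs(D - fd)), 1e-5)
    expect_equal(qr(D)$rank, sp$q)  # full column rank at admissible theta
  }
})

test_that("constrained loadings share Jacobian columns across groups", {
  pair <- make_invariance_pair(4, 2)
  sp <- pair$m0
  th <- c(rep(0.8, 3), c(1, 1.2), rep(1, 8))[seq_len(sp$q)]
  D <- delta_jacobian(th, sp)
  pstar <- 10
  # the shared loading parameter l2 drives moments in both groups
  col <- D[, match("l2", sp$par_names)]
  expect_gt(max(abs(col[1:pstar])), 0)
  expect_gt(max(abs(col[pstar + 1:pstar])), 0)
})
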