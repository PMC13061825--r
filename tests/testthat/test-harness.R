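test_that("full condition grids match the published study sizes", {
  expect_equal(nrow(build_study_grid("study1", "full")), 84L)
  expect_equal(nrow(build_study_grid("study2", "full")), 189L)
  expect_equal(nrow(build_study_grid("study3_gof", "full")), 63L)
  expect_equal(nrow(build_study_grid("study3_invariance", "full")), 189L)
})

test_that("reduced grids preserve the crossing structure", {
  g <- build_study_grid("study2", "reduced")
  expect_equal(nrow(g), length(unique(g$n)) * length(unique(g$p)) *
                 length(unique(g$G)) * length(unique(g$family)))
  expect_true(all(table(g$family) == nrow(g) / length(unique(g$family))))
})

test_that("the adequacy flag implements n/q >= 10", {
  g <- build_study_grid("study1", "full")
  # p = 15: q = 40, adequate from n = 400 up; p = 100: q = 210, never
  expect_true(all(g$adequate[g$p == 15]))
  expect_false(any(g$adequate[g$p == 100]))
  expect_equal(sum(g$adequate), 6L * 7L)  # six adequate cells per family
})

test_that("aggregation metrics satisfy their identities and examples", {
  m <- aggregate_metrics(rep(5, 4))
  expect_equal(unlist(m[c("RMSE", "MAD", "B2.5", "A7.5")]),
               c(RMSE = 0, MAD = 0, B2.5 = 0, A7.5 = 0))
  expect_equal(m$ARR, 100)
  m2 <- aggregate_metrics(c(3, 7))
  expect_equal(c(m2$RMSE, m2$MAD, m2$ARR), c(2, 2, 100))
  m3 <- aggregate_metrics(c(2, 8))
  expect_equal(c(m3$B2.5, m3$ARR, m3$A7.5), c(50, 0, 50))
  # boundary values are acceptable (inclusive band)
  m4 <- aggregate_metrics(c(2.5, 7.5))
  expect_equal(m4$ARR, 100)
  expect_error(aggregate_metrics(numeric(0)), "no rejection rates")
  # Jensen: MAD <= RMSE; band proportions always sum to 100
  set.seed(1)
  for (rep in 1:20) {
    rr <- runif(sample(2:30, 1), 0, 15)
    mm <- aggregate_metrics(rr)
    expect_lte(mm$MAD, mm$RMSE + 1e-12)
    expect_equal(mm$ARR + mm$B2.5 + mm$A7.5, 100)
  }
})

test_that("method labels parse and unknown labels are rejected", {
  x <- pebatest:::parse_method_label("pEBA4_RLS_UG")
  expect_equal(x$base, "RLS")
  expect_equal(x$gamma, "unbiased")
  expect_equal(pebatest:::parse_method_label("SB")$gamma, "biased")
  expect_equal(pebatest:::parse_method_label("RLS")$robustified, FALSE)
  expect_error(pebatest:::parse_method_label("pEBA5x"), "valid")
})

test_that("a single replication yields a degenerate rejection rate", {
  cond <- list(study = "study1", p = 15, G = 1, n = 400, family = "N",
               reps = 1, seed = 3)
  res <- run_condition(cond, methods = c("RLS", "SB"))
  expect_true(all(res$rejection_rate %in% c(0, 100)))
  expect_equal(res$reps_used, c(1, 1))
})

test_that("conditions are deterministic given the seed", {
  cond <- list(study = "study1", p = 15, G = 1, n = 400, family = "VM1",
               reps = 5, seed = 3)
  r1 <- run_condition(cond, methods = c("pEBA4_RLS", "SB_UG"))
  r2 <- run_condition(cond, methods = c("pEBA4_RLS", "SB_UG"))
  expect_identical(r1$rejection_rate, r2$rejection_rate)
  expect_s3_class(autoplot(r1), "ggplot")
})
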