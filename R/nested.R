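#' Nested difference statistic
#'
#' `T_D = T_0 - T_1`, the difference of the fit statistics of the constrained
#' model `M0` and the unconstrained model `M1` computed from the same data.
#' A negative value (possible in finite samples) triggers a warning but is
#' returned as-is.
#'
#' @param fit0,fit1 Converged [cfa_fit][fit_ntml] objects for `M0` and `M1`.
#' @param base `"ML"` or `"RLS"`.
#' @return Scalar difference statistic.
#' @export
t_diff <- function(fit0, fit1, base = c("ML", "RLS")) {
  base <- match.arg(base)
  if (fit0$df <= fit1$df) {
    stop("M0 must be more constrained than M1 (df0 > df1)", call. = FALSE)
  }
  td <- base_statistic(fit0, base) - base_statistic(fit1, base)
  if (td < 0) {
    warning("negative difference statistic (T_0 < T_1)", call. = FALSE)
  }
  td
}

#' Difference weight matrix, single-model (2000) method
#'
#' Computes `U_D` from the unconstrained model `M1` alone: with
#' `M = Delta' V Delta` and `A` the Jacobian of the equality constraints
#' `a(theta) = 0` that carve `M0` out of `M1`, all evaluated at the `M1`
#' estimates,
#' `U_D = V Delta M^{-1} A' (A M^{-1} A')^{-1} A M^{-1} Delta' V`.
#' `U_D Gamma` has exactly `d0 - d1 = nrow(A)` positive eigenvalues, and
#' their sum equals `tr(U_D Gamma)` by construction.
#'
#' @param fit1 Converged fit of the unconstrained model.
#' @param A Constraint Jacobian, `(d0 - d1) x q1`, full row rank (e.g. the
#'   `A` returned by [make_invariance_pair()]).
#' @return An object of class `u_d` holding the factored form
#'   `U_D = X K X'` (elements `X`, `K`), the expected positive eigenvalue
#'   count `d`, and `method = "2000"`.
#' @export
u_d_2000 <- function(fit1, A) {
  stopifnot(inherits(fit1, "cfa_fit"))
  if (!fit1$converged) stop("M1 fit did not converge", call. = FALSE)
  A <- as.matrix(A)
  if (ncol(A) != fit1$spec$q) {
    stop("constraint Jacobian has ", ncol(A), " columns, expected q1 = ",
         fit1$spec$q, call. = FALSE)
  }
  if (qr(A)$rank < nrow(A)) {
    stop("constraint Jacobian is rank deficient", call. = FALSE)
  }
  um <- u_matrix(fit1)
  M <- crossprod(um$Delta, um$V %*% um$Delta)
  Mi <- chol2inv(chol((M + t(M)) / 2))
  MiA <- Mi %*% t(A)                      # q1 x m
  K <- solve(A %*% MiA)                   # m x m, PD
  K <- (K + t(K)) / 2
  X <- um$V %*% (um$Delta %*% MiA)        # (G pstar) x m
  structure(list(X = X, K = K, d = nrow(A), method = "2000"),
            class = "u_d")
}

#' Difference weight matrix, projection-difference (2001) method
#'
#' `U_D = U_0 - U_1`, with each `U` matrix evaluated at its own model's
#' estimates. Agrees with the single-model method in the population but can
#' differ in finite samples; in particular `tr(U_D Gamma)` and the sum of the
#' `d0 - d1` largest eigenvalues of `U_D Gamma` need not coincide.
#'
#' @param fit0,fit1 Converged fits of `M0` and `M1`.
#' @return An object of class `u_d` with elements `U` (full matrix), `d`,
#'   and `method = "2001"`.
#' @export
u_d_2001 <- function(fit0, fit1) {
  if (fit0$df < fit1$df) stop("df0 must be >= df1", call. = FALSE)
  U0 <- u_matrix(fit0)$U
  U1 <- u_matrix(fit1)$U
  structure(list(U = U0 - U1, d = fit0$df - fit1$df, method = "2001"),
            class = "u_d")
}

# Full matrix form of a u_d object.
ud_full <- function(ud) {
  if (!is.null(ud$U)) ud$U else ud$X %*% ud$K %*% t(ud$X)
}

#' Eigenvalue weights of U_D Gamma
#'
#' The `d0 - d1` largest eigenvalues of `U_D Gamma`, sorted increasing, with
#' negative numerical dust clipped at zero. For the factored 2000 form the
#' computation reduces to a dense eigenproblem of dimension `d0 - d1`.
#'
#' @param ud A [u_d][u_d_2000] object.
#' @param gamma Joint `Gamma` estimate (see [gamma_joint()]).
#' @return Numeric vector of length `ud$d`.
#' @export
nested_eigen_weights <- function(ud, gamma) {
  gamma <- unclass(gamma)
  if (!is.null(ud$X)) {
    ek <- eigen(ud$K, symmetric = TRUE)
    khalf <- ek$vectors %*% (sqrt(pmax(ek$values, 0)) * t(ek$vectors))
    core <- crossprod(ud$X, gamma %*% ud$X)
    M <- khalf %*% ((core + t(core)) / 2) %*% khalf
    ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
    return(sort(pmax(ev, 0)))
  }
  ev <- psd_product_eigen(ud$U, gamma)
  sort(pmax(ev[seq_len(ud$d)], 0))
}

#' Satorra-Bentler difference test in its original trace form
#'
#' Scales `T_D` by `c = tr(U_D Gamma) / (d0 - d1)` and refers it to a
#' chi-square with `d0 - d1` degrees of freedom. With the 2000 method this
#' equals the eigenvalue-sum Satorra-Bentler test to numerical precision;
#' with the 2001 method the two can differ, and the trace (hence the scaled
#' statistic) can even be negative, which is reported as-is with a warning.
#'
#' @param t_d Difference statistic.
#' @param ud A [u_d][u_d_2001] object.
#' @param gamma Joint `Gamma` estimate.
#' @return A one-row tibble with columns `procedure`, `statistic`, `df`,
#'   `p_value`.
#' @export
sb_2001_trace <- function(t_d, ud, gamma) {
  d <- ud$d
  tr <- if (!is.null(ud$X)) {
    sum(ud$K * crossprod(ud$X, unclass(gamma) %*% ud$X))
  } else {
    sum(ud$U * t(unclass(gamma)))
  }
  cc <- tr / d
  if (abs(cc) < 1e-12) stop("trace scaling constant is zero", call. = FALSE)
  stat <- t_d / cc
  if (stat < 0) {
    warning("negative scaled difference statistic (trace form)",
            call. = FALSE)
  }
  tibble::tibble(procedure = "SB_2001", statistic = stat, df = d,
                 p_value = pchisq(stat, df = d, lower.tail = FALSE))
}

#' All nested-comparison tests for a fitted model pair
#'
#' Applies every stabilizer/procedure of the goodness-of-fit battery to the
#' difference statistic `T_D` and the `d0 - d1` eigenvalue weights of
#' `U_D Gamma`: nine procedures crossed with base statistic and `Gamma`
#' variant (36 robustified tests), for the requested `U_D` estimator. With
#' `ud_method = "2001"` the additional trace-form test `SB_2001` (ML base,
#' biased `Gamma`) is appended.
#'
#' @param fit0,fit1 Converged fits of the nested pair on the same data.
#' @param data Raw data (data frame with group column, or list of per-group
#'   matrices) for `Gamma` estimation.
#' @param group Grouping column name when `data` is a data frame.
#' @param A Constraint Jacobian for the 2000 method (from
#'   [make_invariance_pair()]).
#' @param ud_method `"2000"` or `"2001"`.
#' @param bases,gamma_variants Subsets of the test battery to compute.
#' @return A tibble with columns `procedure`, `base`, `gamma_variant`,
#'   `ud_method`, `statistic`, `df`, `p_value`.
#' @export
nested_tests <- function(fit0, fit1, data, group = NULL, A = NULL,
                         ud_method = c("2000", "2001"),
                         bases = c("ML", "RLS"),
                         gamma_variants = c("biased", "unbiased")) {
  ud_method <- match.arg(ud_method)
  X_list <- split_groups(data, group, fit1$spec$G)
  ud <- if (ud_method == "2000") {
    if (is.null(A)) stop("the 2000 method needs the constraint Jacobian 'A'",
                         call. = FALSE)
    u_d_2000(fit1, A)
  } else {
    u_d_2001(fit0, fit1)
  }
  d <- fit0$df - fit1$df
  stats <- list()
  for (base in bases) {
    stats[[base]] <- suppressWarnings(t_diff(fit0, fit1, base))
  }
  catalog <- method_catalog(d)
  rows <- list()
  for (variant in gamma_variants) {
    gam <- gamma_joint(X_list, variant)
    lam <- nested_eigen_weights(ud, gam)
    if (sum(lam) <= 0) stop("nonpositive weight sum in nested test",
                            call. = FALSE)
    for (base in bases) {
      for (entry in catalog) {
        res <- robustified_pvalue(entry, max(stats[[base]], 0), lam)
        res$procedure <- test_label(entry$label, base, variant)
        res$base <- base
        res$gamma_variant <- variant
        rows[[length(rows) + 1L]] <- res
      }
    }
    if (ud_method == "2001" && variant == "biased" && "ML" %in% bases) {
      res <- suppressWarnings(sb_2001_trace(stats$ML, ud, gam))
      res$base <- "ML"
      res$gamma_variant <- variant
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  out$ud_method <- ud_method
  out[, c("procedure", "base", "gamma_variant", "ud_method", "statistic",
          "df", "p_value")]
}

#' Weak measurement invariance tests on raw data
#'
#' Convenience wrapper that builds the one-factor invariance pair for the
#' data at hand, fits the unconstrained model group by group (its parameters
#' separate over groups) and the constrained model jointly, and returns the
#' nested test battery.
#'
#' @param data Data frame with one row per observation, numeric indicator
#'   columns and a grouping column.
#' @param group Name of the grouping column.
#' @inheritParams nested_tests
#' @return A list with elements `fit0`, `fit1`, `pair`, and `tests` (the
#'   tibble of [nested_tests()]).
#' @export
weak_invariance_tests <- function(data, group,
                                  ud_method = c("2000", "2001"),
                                  bases = c("ML", "RLS"),
                                  gamma_variants = c("biased", "unbiased")) {
  ud_method <- match.arg(ud_method)
  data <- as.data.frame(data)
  vars <- setdiff(names(data), group)
  vars <- vars[vapply(data[vars], is.numeric, logical(1))]
  p <- length(vars)
  gvals <- sort(unique(data[[group]]))
  G <- length(gvals)
  pair <- make_invariance_pair(p, G)
  S_list <- vector("list", G)
  N_list <- vector("list", G)
  for (g in seq_len(G)) {
    X <- as.matrix(data[data[[group]] == gvals[g], vars, drop = FALSE])
    S_list[[g]] <- sample_cov_biased(X)
    N_list[[g]] <- nrow(X)
  }
  fit1 <- fit_m1_groupwise(S_list, N_list, pair)
  fit0 <- fit_ntml(S_list, N_list, pair$m0,
                   start = m0_start_from_m1(fit1, pair))
  tests <- nested_tests(fit0, fit1, data = lapply(seq_len(G), function(g) {
    as.matrix(data[data[[group]] == gvals[g], vars, drop = FALSE])
  }), A = pair$A, ud_method = ud_method, bases = bases,
  gamma_variants = gamma_variants)
  list(fit0 = fit0, fit1 = fit1, pair = pair, tests = tests)
}

# Fit the unconstrained invariance model group by group: its parameters
# separate, so the joint optimum is the collection of per-group optima.
fit_m1_groupwise <- function(S_list, N_list, pair) {
  m1 <- pair$m1
  G <- m1$G
  p <- m1$p
  single <- make_invariance_pair(p, 1, allow_single_group = TRUE)$m1
  theta <- rep(NA_real_, m1$q)
  F_min <- 0
  conv <- TRUE
  iters <- 0L
  heywood <- FALSE
  N <- sum(unlist(N_list))
  for (g in seq_len(G)) {
    fg <- fit_ntml(list(S_list[[g]]), list(N_list[[g]]), single)
    conv <- conv && fg$converged
    heywood <- heywood || fg$heywood
    iters <- max(iters, fg$n_iterations)
    F_min <- F_min + (N_list[[g]] / N) * fg$F_min
    names_g <- sub("^g1_", sprintf("g%d_", g), single$par_names)
    theta[match(names_g, m1$par_names)] <- fg$theta
  }
  structure(list(
    theta = theta, spec = m1,
    sigma_hat = lapply(seq_len(G), function(g) build_sigma(theta, m1, g)),
    S = S_list, N = unlist(N_list),
    F_min = F_min, df = m1$df, converged = conv, n_iterations = iters,
    heywood = heywood, message = "assembled from per-group fits"
  ), class = "cfa_fit")
}

# Start values for the constrained model from the unconstrained estimates.
m0_start_from_m1 <- function(fit1, pair) {
  m0 <- pair$m0
  m1 <- pair$m1
  G <- m0$G
  p <- m0$p
  w <- fit1$N / sum(fit1$N)
  start <- rep(NA_real_, m0$q)
  for (i in 2:p) {
    lam_g <- vapply(seq_len(G), function(g) {
      fit1$theta[match(sprintf("g%d_l%d", g, i), m1$par_names)]
    }, numeric(1))
    start[match(sprintf("l%d", i), m0$par_names)] <- sum(w * lam_g)
  }
  for (g in seq_len(G)) {
    start[match(sprintf("g%d_phi", g), m0$par_names)] <-
      fit1$theta[match(sprintf("g%d_phi", g), m1$par_names)]
    for (i in seq_len(p)) {
      start[match(sprintf("g%d_psi%d", g, i), m0$par_names)] <-
        fit1$theta[match(sprintf("g%d_psi%d", g, i), m1$par_names)]
    }
  }
  start
}
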