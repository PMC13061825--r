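#' @importFrom stats nlminb cov pchisq pf qchisq rnorm runif var
NULL

# Biased sample covariance (divisor N), the convention of the NTML fit
# function: the N-1 factor enters only through the test statistics.
sample_cov_biased <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  crossprod(Xc) / n
}

# F_NTML(S, Sigma) = log|Sigma| + tr(S Sigma^-1) - log|S| - p, >= 0.
ntml_discrepancy <- function(S, sigma, logdet_S) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(NaN)
  logdet <- 2 * sum(log(diag(ch)))
  sig_inv <- chol2inv(ch)
  logdet + sum(sig_inv * S) - logdet_S - nrow(S)
}

default_start <- function(spec, S_list) {
  theta <- rep(NA_real_, spec$q)
  for (g in seq_len(spec$G)) {
    s_var <- diag(S_list[[g]])
    li <- spec$lambda_idx[[g]]
    theta[li[li > 0L]] <- 0.7
    pi_ <- spec$phi_idx[[g]]
    start_phi <- diag(spec$l)  # variances 1, covariances 0
    theta[pi_[pi_ > 0L]] <- start_phi[pi_ > 0L]
    ri <- spec$psi_idx[[g]]
    start_psi <- diag(s_var / 2, spec$p)
    theta[ri[ri > 0L]] <- start_psi[ri > 0L]
  }
  theta
}

#' Fit a confirmatory factor model by normal-theory maximum likelihood
#'
#' Minimizes the group-size-weighted discrepancy
#' `F(theta) = sum_g (N_g/N) F_NTML(S_g, Sigma_g(theta))` by quasi-Newton
#' iteration with the analytic gradient. `F_NTML` is the usual ML fit
#' function `log|Sigma| + tr(S Sigma^-1) - log|S| - p`, and `S_g` is the
#' biased (divisor `N_g`) sample covariance.
#'
#' @param S_list List of per-group sample covariance matrices (divisor `N`).
#'   A single matrix is accepted for `G = 1`.
#' @param N_list Per-group sample sizes.
#' @param spec A [cfa_spec][new_cfa_spec].
#' @param start Optional start vector of length `q`.
#' @return An object of class `cfa_fit` with elements `theta`, `sigma_hat`
#'   (list), `S` (list), `N` (vector), `F_min`, `df`, `converged`,
#'   `n_iterations`, `heywood`, `spec`.
#' @export
fit_ntml <- function(S_list, N_list, spec, start = NULL) {
  stopifnot(inherits(spec, "cfa_spec"))
  if (is.matrix(S_list)) S_list <- list(S_list)
  G <- spec$G
  if (length(S_list) != G || length(N_list) != G) {
    stop("need one covariance matrix and sample size per group", call. = FALSE)
  }
  p <- spec$p
  logdet_S <- numeric(G)
  for (g in seq_len(G)) {
    S <- S_list[[g]]
    if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8))) {
      stop("sample covariance for group ", g, " is not symmetric",
           call. = FALSE)
    }
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) {
      stop("sample covariance for group ", g, " is not positive definite",
           call. = FALSE)
    }
    logdet_S[g] <- 2 * sum(log(diag(ch)))
    if (N_list[[g]] <= p) {
      warning("group ", g, ": sample size ", N_list[[g]],
              " does not exceed the number of variables", call. = FALSE)
    }
  }
  N <- sum(unlist(N_list))
  w <- unlist(N_list) / N

  objective <- function(theta) {
    val <- 0
    for (g in seq_len(G)) {
      f <- ntml_discrepancy(S_list[[g]], build_sigma(theta, spec, g),
                            logdet_S[g])
      if (!is.finite(f)) return(NaN)
      val <- val + w[g] * f
    }
    val
  }

  gradient <- function(theta) {
    grad <- numeric(spec$q)
    for (g in seq_len(G)) {
      m <- theta_matrices(theta, spec, g)
      sigma <- m$lambda %*% m$phi %*% t(m$lambda) + m$psi
      ch <- tryCatch(chol((sigma + t(sigma)) / 2), error = function(e) NULL)
      if (is.null(ch)) return(rep(NaN, spec$q))
      sig_inv <- chol2inv(ch)
      # dF/dSigma at fixed S
      Gm <- sig_inv - sig_inv %*% S_list[[g]] %*% sig_inv
      Gm <- (Gm + t(Gm)) / 2
      # loadings: dF/dlambda_{ij} = 2 (Gm Lambda Phi)_{ij}
      li <- spec$lambda_idx[[g]]
      free <- li > 0L
      if (any(free)) {
        gl <- 2 * (Gm %*% m$lambda %*% m$phi)
        grad <- grad + w[g] *
          as.vector(rowsum_into(spec$q, li[free], gl[free]))
      }
      # phi: diag (L' Gm L)_jj, off-diag 2 (L' Gm L)_jk
      pi_ <- spec$phi_idx[[g]]
      lowp <- lower.tri(pi_, diag = TRUE) & pi_ > 0L
      if (any(lowp)) {
        gp <- t(m$lambda) %*% Gm %*% m$lambda
        gp2 <- 2 * gp
        diag(gp2) <- diag(gp)
        grad <- grad + w[g] *
          as.vector(rowsum_into(spec$q, pi_[lowp], gp2[lowp]))
      }
      # psi: diag Gm_ii, off-diag 2 Gm_ij
      ri <- spec$psi_idx[[g]]
      lowr <- lower.tri(ri, diag = TRUE) & ri > 0L
      if (any(lowr)) {
        gr <- 2 * Gm
        diag(gr) <- diag(Gm)
        grad <- grad + w[g] *
          as.vector(rowsum_into(spec$q, ri[lowr], gr[lowr]))
      }
    }
    grad
  }

  theta0 <- if (is.null(start)) default_start(spec, S_list) else start
  if (length(theta0) != spec$q) {
    stop("start vector has length ", length(theta0), ", expected ", spec$q,
         call. = FALSE)
  }

  # PORT signals a warning whenever a trial point leaves the PD cone (the
  # objective returns NaN there by design); that is its backtracking
  # mechanism, not a failure, so those warnings are muffled.
  opt <- withCallingHandlers(
    nlminb(theta0, objective, gradient,
           control = list(iter.max = 500L, eval.max = 2000L,
                          rel.tol = 1e-10)),
    warning = function(w) {
      if (grepl("NA/NaN function evaluation", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  theta_hat <- opt$par
  grad_at_opt <- gradient(theta_hat)
  converged <- (opt$convergence == 0L ||
                  (all(is.finite(grad_at_opt)) &&
                     max(abs(grad_at_opt)) < 1e-7)) &&
    is.finite(opt$objective)

  sigma_hat <- lapply(seq_len(G), function(g) build_sigma(theta_hat, spec, g))
  heywood <- FALSE
  for (g in seq_len(G)) {
    m <- theta_matrices(theta_hat, spec, g)
    if (any(diag(m$psi) < 0) || any(diag(m$phi) < 0)) heywood <- TRUE
  }

  structure(list(
    theta = theta_hat,
    spec = spec,
    sigma_hat = sigma_hat,
    S = S_list,
    N = unlist(N_list),
    F_min = max(0, opt$objective),
    df = spec$df,
    converged = converged,
    n_iterations = opt$iterations,
    heywood = heywood,
    message = opt$message
  ), class = "cfa_fit")
}

# Accumulate values into a length-q vector by (possibly duplicated) index.
rowsum_into <- function(q, idx, val) {
  out <- numeric(q)
  s <- rowsum(val, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Fit a confirmatory factor model to raw data
#'
#' Data-frame-first wrapper around [fit_ntml()]: computes per-group biased
#' sample covariances and fits the model.
#'
#' @param data A data frame or matrix of continuous observations, one row per
#'   observation. Non-numeric columns other than `group` are dropped.
#' @param spec A [cfa_spec][new_cfa_spec].
#' @param group Optional name of the grouping column in `data` (required when
#'   `spec$G > 1`). Groups are taken in order of first appearance sorted by
#'   `sort(unique(...))`.
#' @param start Optional start values.
#' @return A `cfa_fit`; see [fit_ntml()].
#' @export
fit_cfa <- function(data, spec, group = NULL, start = NULL) {
  data <- as.data.frame(data)
  if (is.null(group)) {
    if (spec$G != 1L) stop("multi-group spec needs a 'group' column",
                           call. = FALSE)
    X <- as.matrix(data[vapply(data, is.numeric, logical(1))])
    return(fit_ntml(list(sample_cov_biased(X)), list(nrow(X)), spec, start))
  }
  gvals <- sort(unique(data[[group]]))
  if (length(gvals) != spec$G) {
    stop("data has ", length(gvals), " groups but spec has ", spec$G,
         call. = FALSE)
  }
  S_list <- vector("list", spec$G)
  N_list <- vector("list", spec$G)
  for (g in seq_along(gvals)) {
    dg <- data[data[[group]] == gvals[g], setdiff(names(data), group),
               drop = FALSE]
    X <- as.matrix(dg[vapply(dg, is.numeric, logical(1))])
    S_list[[g]] <- sample_cov_biased(X)
    N_list[[g]] <- nrow(X)
  }
  fit_ntml(S_list, N_list, spec, start)
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat("NTML factor model fit\n")
  cat(sprintf("  p = %d, groups = %d, N = %s\n", x$spec$p, x$spec$G,
              paste(x$N, collapse = "/")))
  cat(sprintf("  q = %d free parameters, df = %d\n", x$spec$q, x$df))
  cat(sprintf("  F_min = %.6g, converged: %s (%d iterations)%s\n",
              x$F_min, x$converged, x$n_iterations,
              if (x$heywood) ", Heywood case" else ""))
  invisible(x)
}
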