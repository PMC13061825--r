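#' Confirmatory factor model specifications
#'
#' A `cfa_spec` describes a single- or multi-group confirmatory factor model
#' `Sigma_g(theta) = Lambda_g Phi_g Lambda_g' + Psi_g`. Each matrix entry is
#' either fixed to a value or free; free entries carry labels, and entries
#' sharing a label (possibly across groups) share one parameter. The free
#' parameters are collected into a vector `theta` of length `q`, and the
#' model degrees of freedom are `d = G * p(p+1)/2 - q`.
#'
#' @param lambda_labels,phi_labels,psi_labels Lists (length `G`) of character
#'   matrices; `""` marks a fixed entry, any other string labels a free
#'   parameter. `phi` and `psi` labels/fixed values must be symmetric.
#' @param lambda_fixed,phi_fixed,psi_fixed Lists of numeric matrices holding
#'   the values of fixed entries (ignored at free positions).
#' @return An object of class `cfa_spec` with elements `p`, `l`, `G`, `q`,
#'   `df`, `par_names`, and per-group index/value matrices.
#' @keywords internal
new_cfa_spec <- function(lambda_labels, lambda_fixed,
                         phi_labels, phi_fixed,
                         psi_labels, psi_fixed) {
  G <- length(lambda_labels)
  p <- nrow(lambda_labels[[1]])
  l <- ncol(lambda_labels[[1]])
  for (g in seq_len(G)) {
    stopifnot(
      identical(dim(lambda_labels[[g]]), c(p, l)),
      identical(dim(phi_labels[[g]]), c(l, l)),
      identical(dim(psi_labels[[g]]), c(p, p)),
      identical(phi_labels[[g]], t(phi_labels[[g]])),
      identical(psi_labels[[g]], t(psi_labels[[g]]))
    )
  }

  # Parameter order: first appearance, scanning groups, lambda column-major,
  # then lower triangles of phi and psi.
  labels <- character(0)
  for (g in seq_len(G)) {
    lab <- c(
      as.vector(lambda_labels[[g]]),
      phi_labels[[g]][lower.tri(phi_labels[[g]], diag = TRUE)],
      psi_labels[[g]][lower.tri(psi_labels[[g]], diag = TRUE)]
    )
    labels <- c(labels, lab[lab != ""])
  }
  par_names <- unique(labels)
  q <- length(par_names)

  idx_of <- function(lab) {
    out <- match(lab, par_names)
    out[lab == ""] <- 0L
    matrix(out, nrow(lab), ncol(lab))
  }
  sym_idx <- function(lab) {
    m <- idx_of(lab)
    m[upper.tri(m)] <- t(m)[upper.tri(m)]
    m
  }

  spec <- list(
    p = p, l = l, G = G, q = q,
    df = G * p * (p + 1L) / 2L - q,
    par_names = par_names,
    lambda_idx = lapply(lambda_labels, idx_of),
    lambda_fixed = lambda_fixed,
    phi_idx = lapply(phi_labels, sym_idx),
    phi_fixed = phi_fixed,
    psi_idx = lapply(psi_labels, sym_idx),
    psi_fixed = psi_fixed
  )
  if (spec$df < 0) {
    stop("model is under-identified: more free parameters (", q,
         ") than sample moments (", G * p * (p + 1L) / 2L, ")", call. = FALSE)
  }
  class(spec) <- "cfa_spec"
  spec
}

#' @export
print.cfa_spec <- function(x, ...) {
  cat("Confirmatory factor model specification\n")
  cat(sprintf("  observed variables p: %d, factors l: %d, groups G: %d\n",
              x$p, x$l, x$G))
  cat(sprintf("  free parameters q: %d, degrees of freedom: %d\n", x$q, x$df))
  invisible(x)
}

#' Model degrees of freedom
#'
#' `d = G * p(p+1)/2 - q`, the number of non-redundant sample moments minus
#' the number of free parameters.
#'
#' @param spec A [cfa_spec][new_cfa_spec] object.
#' @return Integer degrees of freedom.
#' @export
model_degrees_of_freedom <- function(spec) {
  stopifnot(inherits(spec, "cfa_spec"))
  spec$df
}

# Resolve theta into (Lambda, Phi, Psi) for one group.
theta_matrices <- function(theta, spec, group = 1L) {
  if (length(theta) != spec$q) {
    stop("theta has length ", length(theta), ", expected ", spec$q,
         call. = FALSE)
  }
  pick <- function(idx, fixed) {
    m <- fixed
    free <- idx > 0L
    m[free] <- theta[idx[free]]
    m
  }
  list(
    lambda = pick(spec$lambda_idx[[group]], spec$lambda_fixed[[group]]),
    phi    = pick(spec$phi_idx[[group]],    spec$phi_fixed[[group]]),
    psi    = pick(spec$psi_idx[[group]],    spec$psi_fixed[[group]])
  )
}

# Extract theta from per-group matrices (inverse of theta_matrices);
# entries sharing a parameter must agree.
matrices_to_theta <- function(mats, spec) {
  theta <- rep(NA_real_, spec$q)
  put <- function(theta, idx, m) {
    free <- which(idx > 0L)
    theta[idx[free]] <- m[free]
    theta
  }
  for (g in seq_len(spec$G)) {
    theta <- put(theta, spec$lambda_idx[[g]], mats[[g]]$lambda)
    theta <- put(theta, spec$phi_idx[[g]], mats[[g]]$phi)
    theta <- put(theta, spec$psi_idx[[g]], mats[[g]]$psi)
  }
  theta
}

#' Model-implied covariance matrix
#'
#' Evaluates `Sigma_g(theta) = Lambda_g Phi_g Lambda_g' + Psi_g`.
#'
#' @param theta Parameter vector of length `q`.
#' @param spec A `cfa_spec`.
#' @param group Group index.
#' @return A symmetric `p x p` matrix.
#' @export
build_sigma <- function(theta, spec, group = 1L) {
  m <- theta_matrices(theta, spec, group)
  s <- m$lambda %*% m$phi %*% t(m$lambda) + m$psi
  (s + t(s)) / 2
}

#' Jacobian of the stacked model-implied moments
#'
#' Analytic derivative matrix of the stacked per-group `vech(Sigma_g(theta))`
#' with respect to `theta`. Rows are ordered group by group; columns follow
#' the parameter index of `spec`.
#'
#' @inheritParams build_sigma
#' @return A `G * p(p+1)/2` by `q` matrix.
#' @export
delta_jacobian <- function(theta, spec) {
  p <- spec$p
  pstar <- p * (p + 1L) / 2L
  lowtri <- lower.tri(diag(p), diag = TRUE)
  Delta <- matrix(0, spec$G * pstar, spec$q)
  for (g in seq_len(spec$G)) {
    m <- theta_matrices(theta, spec, g)
    LP <- m$lambda %*% m$phi                      # p x l
    rows <- (g - 1L) * pstar + seq_len(pstar)
    # loadings
    idx <- spec$lambda_idx[[g]]
    for (k in which(idx > 0L)) {
      i <- (k - 1L) %% p + 1L
      j <- (k - 1L) %/% p + 1L
      dS <- matrix(0, p, p)
      dS[i, ] <- dS[i, ] + LP[, j]
      dS[, i] <- dS[, i] + LP[, j]
      Delta[rows, idx[k]] <- Delta[rows, idx[k]] + dS[lowtri]
    }
    # factor covariances (lower triangle, symmetric parameter)
    pidx <- spec$phi_idx[[g]]
    for (j in seq_len(spec$l)) {
      for (i in j:spec$l) {
        if (pidx[i, j] == 0L) next
        dS <- if (i == j) {
          tcrossprod(m$lambda[, i])
        } else {
          tcrossprod(m$lambda[, i], m$lambda[, j]) +
            tcrossprod(m$lambda[, j], m$lambda[, i])
        }
        Delta[rows, pidx[i, j]] <- Delta[rows, pidx[i, j]] + dS[lowtri]
      }
    }
    # residual (co)variances
    ridx <- spec$psi_idx[[g]]
    for (j in seq_len(p)) {
      for (i in j:p) {
        if (ridx[i, j] == 0L) next
        dS <- matrix(0, p, p)
        dS[i, j] <- dS[i, j] + 1
        dS[j, i] <- dS[j, i] + 1
        if (i == j) dS[i, j] <- 1
        Delta[rows, ridx[i, j]] <- Delta[rows, ridx[i, j]] + dS[lowtri]
      }
    }
  }
  Delta
}

#' Single-group factor model specification
#'
#' Builds a `cfa_spec` for one group from a loading pattern: each observed
#' variable loads on exactly one factor, factor variances are fixed at 1,
#' factor correlations are free, and residual variances are free (the
#' standardized-factor identification convention).
#'
#' @param factor_of Integer vector of length `p`; `factor_of[i]` is the factor
#'   on which variable `i` loads.
#' @return A `cfa_spec` with `q = p + l(l-1)/2 + p` free parameters.
#' @export
simple_cfa_spec <- function(factor_of) {
  p <- length(factor_of)
  l <- max(factor_of)
  lam_lab <- matrix("", p, l)
  for (i in seq_len(p)) lam_lab[i, factor_of[i]] <- sprintf("l%d", i)
  lam_fix <- matrix(0, p, l)
  phi_lab <- matrix("", l, l)
  for (j in seq_len(l)) for (i in seq_len(l)) {
    if (i != j) phi_lab[i, j] <- sprintf("phi%d_%d", min(i, j), max(i, j))
  }
  phi_fix <- diag(l)
  psi_lab <- matrix("", p, p)
  diag(psi_lab) <- sprintf("psi%d", seq_len(p))
  psi_fix <- matrix(0, p, p)
  new_cfa_spec(list(lam_lab), list(lam_fix), list(phi_lab), list(phi_fix),
               list(psi_lab), list(psi_fix))
}

#' Five-factor goodness-of-fit model specification
#'
#' The five-factor model used in the goodness-of-fit simulations: `p/5`
#' indicators per factor, unit factor variances, free loadings, free factor
#' correlations and free residual variances, giving `q = 2p + 10`.
#'
#' @param p Number of observed variables; must be divisible by 5.
#' @return A `cfa_spec`.
#' @export
study_gof_spec <- function(p) {
  if (p %% 5 != 0) stop("'p' must be divisible by 5", call. = FALSE)
  simple_cfa_spec(rep(1:5, each = p / 5))
}

#' Nested specification pair for weak invariance testing
#'
#' Builds the constrained model `M0` (factor loadings equal across groups)
#' and the unconstrained model `M1` (loadings free per group) for a
#' one-factor model on `p` variables in `G` groups. Both models use
#' marker-variable identification: the first loading is fixed at 1 and the
#' factor variance is free in every group, so that `M0` is a *linear*
#' restriction of `M1` (loading equalities across groups). Residual variances
#' are free in every group.
#'
#' Degrees of freedom: `df1 = G p(p+1)/2 - G(2p)`,
#' `df0 = df1 + (G-1)(p-1)`.
#'
#' @param p Number of observed variables (at least 3).
#' @param G Number of groups (at least 2, unless `allow_single_group`).
#' @param allow_single_group If `TRUE`, `G = 1` returns `m0` identical to
#'   `m1` with an empty constraint matrix instead of raising.
#' @return A list with elements `m0`, `m1` (both `cfa_spec`) and `A`, the
#'   `(G-1)(p-1) x q1` Jacobian of the equality constraints `a(theta) = 0`
#'   that carve `M0` out of `M1`.
#' @export
make_invariance_pair <- function(p, G, allow_single_group = FALSE) {
  if (p < 3) stop("one-factor model needs p >= 3 for identification",
                  call. = FALSE)
  if (G < 2 && !allow_single_group) {
    stop("invariance testing needs G >= 2 groups", call. = FALSE)
  }

  lam_fix <- matrix(0, p, 1)
  lam_fix[1, 1] <- 1
  psi_fix <- matrix(0, p, p)

  group_spec_labels <- function(lam_label_fun) {
    lam_lab <- vector("list", G)
    phi_lab <- vector("list", G)
    psi_lab <- vector("list", G)
    for (g in seq_len(max(G, 1L))) {
      lab <- matrix("", p, 1)
      if (p > 1) lab[2:p, 1] <- lam_label_fun(g, 2:p)
      lam_lab[[g]] <- lab
      phi_lab[[g]] <- matrix(sprintf("g%d_phi", g), 1, 1)
      pl <- matrix("", p, p)
      diag(pl) <- sprintf("g%d_psi%d", g, seq_len(p))
      psi_lab[[g]] <- pl
    }
    list(lambda = lam_lab, phi = phi_lab, psi = psi_lab)
  }

  lab1 <- group_spec_labels(function(g, i) sprintf("g%d_l%d", g, i))
  lab0 <- group_spec_labels(function(g, i) sprintf("l%d", i))

  mk <- function(lab) {
    new_cfa_spec(lab$lambda, replicate(G, lam_fix, simplify = FALSE),
                 lab$phi, replicate(G, diag(1), simplify = FALSE),
                 lab$psi, replicate(G, psi_fix, simplify = FALSE))
  }
  m1 <- mk(lab1)
  m0 <- mk(lab0)

  # Linear constraints carving M0 out of M1: lambda_{g,i} - lambda_{1,i} = 0
  n_con <- (G - 1L) * (p - 1L)
  A <- matrix(0, n_con, m1$q)
  if (n_con > 0) {
    r <- 0L
    for (g in 2:G) {
      for (i in 2:p) {
        r <- r + 1L
        A[r, match(sprintf("g%d_l%d", g, i), m1$par_names)] <- 1
        A[r, match(sprintf("g1_l%d", i), m1$par_names)] <- -1
      }
    }
  }
  list(m0 = m0, m1 = m1, A = A)
}
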