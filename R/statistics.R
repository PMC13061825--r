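#' ML and RLS fit statistics
#'
#' `t_ml()` is the likelihood-ratio-type statistic
#' `(N - 1) * F_min` with `N` the total sample size and `F_min` the minimized
#' group-weighted NTML discrepancy. `t_rls()` is Browne's reweighted least
#' squares statistic `sum_g (N_g / 2) tr([I - Sigma_g(theta)^{-1} S_g]^2)`,
#' which reduces to `N/2 tr([I - Sigma^{-1} S]^2)` for a single group and
#' shares the asymptotic law of `t_ml()`.
#'
#' @param fit A converged [cfa_fit][fit_ntml].
#' @return A nonnegative scalar.
#' @export
t_ml <- function(fit) {
  stopifnot(inherits(fit, "cfa_fit"))
  if (!fit$converged) stop("fit did not converge; statistic not available",
                           call. = FALSE)
  (sum(fit$N) - 1) * fit$F_min
}

#' @rdname t_ml
#' @export
t_rls <- function(fit) {
  stopifnot(inherits(fit, "cfa_fit"))
  if (!fit$converged) stop("fit did not converge; statistic not available",
                           call. = FALSE)
  total <- 0
  for (g in seq_len(fit$spec$G)) {
    sig_inv <- tryCatch(chol2inv(chol(fit$sigma_hat[[g]])),
                        error = function(e) NULL)
    if (is.null(sig_inv)) {
      stop("model-implied covariance is singular in group ", g, call. = FALSE)
    }
    R <- diag(fit$spec$p) - sig_inv %*% fit$S[[g]]
    total <- total + fit$N[g] / 2 * sum(R * t(R))
  }
  max(0, total)
}

base_statistic <- function(fit, base = c("ML", "RLS")) {
  base <- match.arg(base)
  if (base == "ML") t_ml(fit) else t_rls(fit)
}
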