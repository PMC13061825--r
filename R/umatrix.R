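#' Normal-theory weight matrix V in vech coordinates
#'
#' `V = 1/2 D_p' (Sigma^{-1} x Sigma^{-1}) D_p`, computed entrywise as
#' `V[(ij),(kl)] = (A_ik A_jl + A_il A_jk) w_ij w_kl` with `A = Sigma^{-1}`
#' and `w_ij = 1/2` when `i = j`, `1` otherwise, avoiding the `p^2 x p^2`
#' Kronecker product. `V` is the inverse of the normal-theory `Gamma` at
#' `Sigma`.
#'
#' @param sigma Symmetric positive definite `p x p` matrix.
#' @return A `p(p+1)/2` square symmetric matrix.
#' @export
v_matrix <- function(sigma) {
  A <- chol2inv(chol(sigma))
  ij <- which(lower.tri(sigma, diag = TRUE), arr.ind = TRUE)
  iv <- ij[, 1]; jv <- ij[, 2]
  w <- ifelse(iv == jv, 0.5, 1)
  (A[iv, iv, drop = FALSE] * A[jv, jv, drop = FALSE] +
     A[iv, jv, drop = FALSE] * A[jv, iv, drop = FALSE]) * tcrossprod(w)
}

#' Residual weight matrix U of a fitted model
#'
#' `U = V - V Delta (Delta' V Delta)^{-1} Delta' V`, the weight matrix whose
#' product with `Gamma` carries the weights of the limiting chi-square
#' mixture of the fit statistics. For multi-group fits `V` is block-diagonal
#' with blocks `(N_g/N) V_g`, matching the fit-function weighting, and
#' `Delta` stacks the per-group moment Jacobians.
#'
#' @param fit A converged [cfa_fit][fit_ntml].
#' @return A list of class `u_matrix` with elements `U`, `V`, `Delta`, and
#'   `d` (the expected rank of `U Gamma`).
#' @export
u_matrix <- function(fit) {
  stopifnot(inherits(fit, "cfa_fit"))
  if (!fit$converged) {
    stop("fit did not converge; refusing to compute U", call. = FALSE)
  }
  w <- fit$N / sum(fit$N)
  Vb <- block_diag(lapply(seq_len(fit$spec$G), function(g) {
    w[g] * v_matrix(fit$sigma_hat[[g]])
  }))
  Delta <- delta_jacobian(fit$theta, fit$spec)
  VD <- Vb %*% Delta
  M <- crossprod(Delta, VD)
  M <- (M + t(M)) / 2
  Mi <- tryCatch(chol2inv(chol(M)), error = function(e) NULL)
  if (is.null(Mi)) {
    sv <- svd(M, nu = 0, nv = 0)$d
    bad <- which(sv < max(sv) * 1e-12)
    stop("Delta' V Delta is rank deficient; parameters involved: ",
         paste(fit$spec$par_names[bad], collapse = ", "), call. = FALSE)
  }
  U <- Vb - VD %*% Mi %*% t(VD)
  U <- (U + t(U)) / 2
  structure(list(U = U, V = Vb, Delta = Delta, d = fit$df),
            class = "u_matrix")
}

#' Eigenvalue weights of U Gamma
#'
#' Extracts the `d` largest eigenvalues of `U Gamma`, sorted in increasing
#' order. Both matrices are symmetric positive semidefinite, so the product
#' has a real nonnegative spectrum; the computation uses the symmetric form
#' `Gamma^{1/2} U Gamma^{1/2}`. Negative numerical dust is clipped at zero,
#' and an error is raised if materially more than `d` eigenvalues are
#' nonzero.
#'
#' @param U A [u_matrix] object, or the `U` matrix itself.
#' @param gamma A `Gamma` estimate of matching dimension.
#' @param d Number of positive eigenvalues expected (defaults to `U$d`).
#' @return Numeric vector of length `d`, sorted increasing.
#' @export
eigen_weights <- function(U, gamma, d = NULL) {
  if (inherits(U, "u_matrix")) {
    if (is.null(d)) d <- U$d
    U <- U$U
  }
  if (is.null(d)) stop("'d' must be supplied when U is a plain matrix",
                       call. = FALSE)
  if (d == 0) return(numeric(0))
  ev <- psd_product_eigen(U, unclass(gamma))
  tol <- max(abs(ev[1]), 1) * 1e-6
  if (length(ev) > d && abs(ev[d + 1]) > tol * 100) {
    stop("more than d = ", d, " eigenvalues of U Gamma are nonzero; ",
         "the model and Gamma are inconsistent", call. = FALSE)
  }
  sort(pmax(ev[seq_len(d)], 0))
}

# Eigenvalues (decreasing) of the product of two symmetric PSD matrices,
# via the symmetric form G^{1/2} U G^{1/2}.
psd_product_eigen <- function(U, gamma) {
  eg <- eigen((gamma + t(gamma)) / 2, symmetric = TRUE)
  pos <- pmax(eg$values, 0)
  half <- eg$vectors %*% (sqrt(pos) * t(eg$vectors))
  M <- half %*% U %*% half
  eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
}
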