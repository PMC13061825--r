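#' Asymptotic covariance matrix of sample covariances
#'
#' Estimates `Gamma`, the asymptotic covariance matrix of
#' `sqrt(n) * vech(S)`, from raw data. The biased (plug-in) variant replaces
#' population fourth-order moments by sample averages with divisor `n`:
#' entry `((i,j),(k,l))` is `m_ijkl - s_ij s_kl` with all moments centered at
#' the sample mean. The unbiased variant applies exact finite-sample
#' coefficient corrections so that the estimator is unbiased for `Gamma`
#' under i.i.d. sampling; it combines the same fourth-moment matrix with the
#' covariance outer product and the normal-theory term.
#'
#' @param X An `n x p` numeric matrix or data frame of observations.
#' @return A symmetric `p(p+1)/2` square matrix of class `gamma_estimate`
#'   with attributes `variant` and `n`.
#' @seealso [gamma_normal_theory_pop()] for the normal-theory value at a
#'   known covariance matrix.
#' @export
gamma_adf <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 observations to estimate fourth moments",
                  call. = FALSE)
  Y <- centered_sq_products(X)
  s <- colMeans(Y)                       # vech of biased sample covariance
  gam <- crossprod(Y) / n - tcrossprod(s)
  structure((gam + t(gam)) / 2, variant = "biased", n = n,
            class = c("gamma_estimate", "matrix"))
}

#' @rdname gamma_adf
#' @export
gamma_unbiased <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 6) stop("need at least 6 observations for the unbiased variant",
                  call. = FALSE)
  Y <- centered_sq_products(X)
  M <- crossprod(Y) / n                  # fourth-moment matrix, divisor n
  S_u <- cov(X)                          # unbiased covariance, divisor n-1
  s <- vech(S_u)
  nt <- gamma_normal_theory(S_u)         # entries s_ik s_jl + s_il s_jk
  a <- n * (n^2 - n + 2) / ((n - 1) * (n - 2) * (n - 3))
  b <- -(n^2 - 1) / (n * (n - 3))
  cc <- -2 * (n - 1)^2 / (n * (n - 2) * (n - 3))
  gam <- a * M + b * tcrossprod(s) + cc * nt
  structure((gam + t(gam)) / 2, variant = "unbiased", n = n,
            class = c("gamma_estimate", "matrix"))
}

# n x p(p+1)/2 matrix whose row t is vech of (x_t - xbar)(x_t - xbar)'.
centered_sq_products <- function(X) {
  p <- ncol(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ij <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  # lower.tri scans column-wise: matches the vech ordering
  Xc[, ij[, 1], drop = FALSE] * Xc[, ij[, 2], drop = FALSE]
}

#' Normal-theory asymptotic covariance at a known covariance matrix
#'
#' `2 D_p^+ (Sigma %x% Sigma) D_p^+'`, the value of `Gamma` under
#' multivariate normality; used as a population oracle in tests and for the
#' unbiased estimator's normal-theory term.
#'
#' @param sigma A symmetric positive definite matrix.
#' @return A `p(p+1)/2` square matrix.
#' @export
gamma_normal_theory_pop <- function(sigma) {
  gamma_normal_theory(sigma)
}

#' Estimate Gamma per group and assemble the joint block-diagonal matrix
#'
#' For multi-group models the joint `Gamma` is block-diagonal with blocks
#' `Gamma_g / (N_g / N)`: the asymptotic covariance of
#' `sqrt(N) vech(S_g)` rather than `sqrt(N_g) vech(S_g)`. This convention
#' pairs with the `N_g / N` weighting of the fit function, so that the
#' eigenvalues of `U Gamma` do not depend on how the group scaling is split
#' between the two matrices.
#'
#' @param X_list List of per-group data matrices.
#' @param variant `"biased"` or `"unbiased"` (`"UG"` is accepted as an alias).
#' @return A block-diagonal `gamma_estimate` of dimension
#'   `G * p(p+1)/2`.
#' @export
gamma_joint <- function(X_list, variant = c("biased", "unbiased", "UG")) {
  variant <- match.arg(variant)
  if (variant == "UG") variant <- "unbiased"
  if (is.matrix(X_list) || is.data.frame(X_list)) X_list <- list(X_list)
  est <- if (variant == "biased") gamma_adf else gamma_unbiased
  N_g <- vapply(X_list, nrow, numeric(1))
  N <- sum(N_g)
  blocks <- lapply(seq_along(X_list), function(g) {
    unclass(est(X_list[[g]])) * (N / N_g[g])
  })
  structure(block_diag(blocks), variant = variant, n = N,
            class = c("gamma_estimate", "matrix"))
}

block_diag <- function(blocks) {
  dims <- vapply(blocks, nrow, integer(1))
  out <- matrix(0, sum(dims), sum(dims))
  at <- 0L
  for (b in blocks) {
    idx <- at + seq_len(nrow(b))
    out[idx, idx] <- b
    at <- at + nrow(b)
  }
  out
}
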