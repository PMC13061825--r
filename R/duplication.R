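#' Half-vectorization of a symmetric matrix
#'
#' Stacks the lower triangle (including the diagonal) of a square matrix
#' column-wise into a vector of length `p(p+1)/2`.
#'
#' @param A A square matrix.
#' @return Numeric vector of length `p(p+1)/2`.
#' @examples
#' vech(matrix(c(1, 2, 2, 3), 2))
#' @export
vech <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  A[lower.tri(A, diag = TRUE)]
}

#' Inverse half-vectorization
#'
#' Reconstructs the symmetric `p x p` matrix whose lower triangle
#' (stacked column-wise) is `v`.
#'
#' @param v Numeric vector of length `p(p+1)/2`.
#' @return A symmetric `p x p` matrix.
#' @export
vech_inv <- function(v) {
  p <- (sqrt(8 * length(v) + 1) - 1) / 2
  if (abs(p - round(p)) > 1e-8) {
    stop("length(v) is not of the form p(p+1)/2", call. = FALSE)
  }
  p <- round(p)
  A <- matrix(0, p, p)
  A[lower.tri(A, diag = TRUE)] <- v
  A <- A + t(A)
  diag(A) <- diag(A) / 2
  A
}

#' Duplication matrix
#'
#' Returns the `p^2 x p(p+1)/2` duplication matrix `D_p` satisfying
#' `D_p %*% vech(A) == vec(A)` for every symmetric `p x p` matrix `A`.
#'
#' @param p Matrix dimension, a positive integer.
#' @return A `p^2 x p(p+1)/2` 0/1 matrix.
#' @examples
#' A <- matrix(c(1, 2, 2, 3), 2)
#' all.equal(as.vector(A), as.vector(duplication_matrix(2) %*% vech(A)))
#' @export
duplication_matrix <- function(p) {
  if (length(p) != 1L || !is.finite(p) || p < 1 || p != round(p)) {
    stop("'p' must be a positive integer", call. = FALSE)
  }
  p <- as.integer(p)
  pstar <- p * (p + 1L) / 2L
  D <- matrix(0, p * p, pstar)
  # column index in vech for entry (i, j), i >= j (lower triangle, column-wise)
  k <- 0L
  for (j in seq_len(p)) {
    for (i in j:p) {
      k <- k + 1L
      D[(j - 1L) * p + i, k] <- 1
      if (i != j) D[(i - 1L) * p + j, k] <- 1
    }
  }
  D
}

#' Moore-Penrose inverse of the duplication matrix
#'
#' `D_p^+ = (D_p' D_p)^{-1} D_p'` maps `vec(A)` of a symmetric `A` to
#' `vech(A)`. `D_p' D_p` is diagonal (entries 1 on diagonal positions, 2
#' off-diagonal), so the inverse is formed directly.
#'
#' @param p Matrix dimension.
#' @return A `p(p+1)/2 x p^2` matrix.
#' @export
duplication_pinv <- function(p) {
  D <- duplication_matrix(p)
  t(D) / colSums(D)
}

# Normal-theory asymptotic covariance of vech(S): 2 D+ (Sigma x Sigma) D+'
gamma_normal_theory <- function(sigma) {
  p <- nrow(sigma)
  Dp <- duplication_pinv(p)
  2 * Dp %*% (sigma %x% sigma) %*% t(Dp)
}
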