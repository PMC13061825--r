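#' Fleishman power-method coefficients
#'
#' Finds `(a, b, c, d)` such that `Y = a + b Z + c Z^2 + d Z^3` with
#' `Z ~ N(0,1)` has mean 0, variance 1, the requested skewness and the
#' requested excess kurtosis (`a = -c` enforces the zero mean). The moment
#' system is solved by Newton iteration from a grid of starting values; an
#' error names the feasibility boundary if no root exists.
#'
#' @param skew Target skewness.
#' @param exkurt Target excess kurtosis.
#' @return Named numeric vector `c(a, b, c, d)`.
#' @examples
#' fleishman_coefficients(0, 0)   # c(0, 1, 0, 0)
#' @export
fleishman_coefficients <- function(skew, exkurt) {
  if (skew == 0 && exkurt == 0) {
    return(c(a = 0, b = 1, c = 0, d = 0))
  }
  if (exkurt < skew^2 - 2) {
    stop(sprintf(paste0("(skew = %.3g, excess kurtosis = %.3g) violates the ",
                        "moment inequality exkurt >= skew^2 - 2"),
                 skew, exkurt), call. = FALSE)
  }
  resid <- function(th) {
    b <- th[1]; cc <- th[2]; d <- th[3]
    c(b^2 + 6 * b * d + 2 * cc^2 + 15 * d^2 - 1,
      2 * cc * (b^2 + 24 * b * d + 105 * d^2 + 2) - skew,
      24 * (b * d + cc^2 * (1 + b^2 + 28 * b * d) +
              d^2 * (12 + 48 * b * d + 141 * cc^2 + 225 * d^2)) - exkurt)
  }
  newton <- function(th) {
    for (it in 1:200) {
      f <- resid(th)
      if (max(abs(f)) < 1e-12) return(th)
      J <- numeric_jacobian(resid, th)
      step <- tryCatch(solve(J, f), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      # damped update
      lam <- 1
      repeat {
        th_new <- th - lam * step
        if (sum(resid(th_new)^2) < sum(f^2) || lam < 1e-6) break
        lam <- lam / 2
      }
      th <- th_new
    }
    if (max(abs(resid(th))) < 1e-10) th else NULL
  }
  starts <- list(c(0.9, skew / 6, 0.03), c(0.95, skew / 8, 0.01),
                 c(0.8, skew / 8, 0.05), c(0.7, skew / 10, 0.1),
                 c(1, 0.1 * sign(skew + 1e-12), 0),
                 c(0.5, skew / 4, 0.2), c(0.3, skew / 8, 0.3))
  # the moment system can have several real roots; keep the canonical one:
  # among roots with b > 0, maximize b^2 + 6bd + 9d^2, the linear coefficient
  # of the pairwise correlation map, which maximizes the reachable range of
  # intermediate correlations
  range_coef <- function(th) th[1]^2 + 6 * th[1] * th[3] + 9 * th[3]^2
  best <- NULL
  for (s in starts) {
    th <- newton(s)
    if (!is.null(th) && th[1] > 0 &&
        (is.null(best) || range_coef(th) > range_coef(best))) {
      best <- th
    }
  }
  if (is.null(best)) {
    stop(sprintf(paste0("no Fleishman solution found for (skew = %.3g, ",
                        "excess kurtosis = %.3g); the pair lies outside the ",
                        "power method's feasibility region"),
                 skew, exkurt), call. = FALSE)
  }
  c(a = -best[2], b = best[1], c = best[2], d = best[3])
}

numeric_jacobian <- function(f, x, eps = 1e-7) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    xp <- x; xp[j] <- xp[j] + eps
    xm <- x; xm[j] <- xm[j] - eps
    J[, j] <- (f(xp) - f(xm)) / (2 * eps)
  }
  J
}

fleishman_transform <- function(z, coef) {
  coef[["a"]] + coef[["b"]] * z + coef[["c"]] * z^2 + coef[["d"]] * z^3
}
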