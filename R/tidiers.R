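#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted factor model
#'
#' @param x A [cfa_fit][fit_ntml].
#' @param ... Unused.
#' @return A tibble with one row per free parameter (`term`, `estimate`).
#' @export
tidy.cfa_fit <- function(x, ...) {
  tibble::tibble(term = x$spec$par_names, estimate = x$theta)
}

#' One-row summary of a fitted factor model
#'
#' @param x A [cfa_fit][fit_ntml].
#' @param ... Unused.
#' @return A one-row tibble with the discrepancy minimum, both chi-square
#'   statistics and their naive normal-theory p values, degrees of freedom,
#'   total sample size and convergence diagnostics.
#' @export
glance.cfa_fit <- function(x, ...) {
  tml <- if (x$converged) t_ml(x) else NA_real_
  trls <- if (x$converged) t_rls(x) else NA_real_
  tibble::tibble(
    F_min = x$F_min,
    statistic_ml = tml,
    statistic_rls = trls,
    df = x$df,
    p_value_ml = pchisq(tml, x$df, lower.tail = FALSE),
    p_value_rls = pchisq(trls, x$df, lower.tail = FALSE),
    n_obs = sum(x$N),
    n_groups = x$spec$G,
    converged = x$converged,
    heywood = x$heywood,
    n_iterations = x$n_iterations
  )
}

#' Plot rejection rates of a Monte Carlo run
#'
#' Bar chart of per-method rejection rates with the nominal level and the
#' Bradley acceptability band `[2.5, 7.5]` marked.
#'
#' @param object A `peba_mc` tibble from [run_condition()] (or several bound
#'   together).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.peba_mc <- function(object, ...) {
  df <- as.data.frame(object)
  df$condition <- interaction(df$family, df$n, df$p, df$G, drop = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method,
                                   y = .data$rejection_rate,
                                   fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 5, linetype = 2) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = 2.5,
                      ymax = 7.5, alpha = 0.12) +
    ggplot2::labs(x = NULL, y = "rejection rate (%)",
                  fill = "condition") +
    ggplot2::theme_minimal()
}

#' Plot an eigenvalue stabilization
#'
#' Shows the raw eigenvalues of `U Gamma` against their index together with a
#' stabilized version, visualizing what the block averaging does.
#'
#' @param raw Raw eigenvalues, sorted increasing.
#' @param method,nblocks Stabilizer, see [stabilize()].
#' @return A ggplot object.
#' @export
plot_stabilization <- function(raw, method = "pEBA", nblocks = 4) {
  lam <- stabilize(raw, method, nblocks)
  df <- tibble::tibble(
    index = rep(seq_along(raw), 2),
    value = c(raw, lam),
    which = rep(c("raw", "stabilized"), each = length(raw))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$value,
                                   colour = .data$which)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = mean(raw), linetype = 3) +
    ggplot2::labs(x = "eigenvalue index", y = "weight", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
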