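#' Eigenvalue-based mixture p value
#'
#' Stabilizes the raw eigenvalue weights with the requested method and
#' evaluates the weighted chi-square mixture tail at the statistic.
#'
#' @param statistic Nonnegative test statistic.
#' @param raw_weights Raw eigenvalues of `U Gamma`, sorted increasing.
#' @param method Stabilizer, see [stabilize()].
#' @param nblocks Number of blocks for `EBA`/`pEBA`.
#' @return A one-row tibble with columns `procedure`, `statistic`, `df`,
#'   `p_value`.
#' @export
pvalue_eigen <- function(statistic, raw_weights,
                         method = c("ALL", "SB", "EBA", "pEBA", "pEBAdf",
                                    "pOLS2"),
                         nblocks = NULL) {
  method <- match.arg(method)
  lam <- stabilize(raw_weights, method, nblocks)
  p <- tail_prob_weighted_chisq(statistic, lam)
  label <- if (method %in% c("EBA", "pEBA")) paste0(method, nblocks) else
    method
  tibble::tibble(procedure = label, statistic = statistic,
                 df = length(raw_weights), p_value = p)
}

#' Scaled-and-shifted p value
#'
#' `T_SS = a T + d - b` with `a = sqrt(d / tr((U Gamma)^2))` and
#' `b = sqrt(d tr(U Gamma)^2 / tr((U Gamma)^2))`; the traces are the power
#' sums of the eigenvalue weights. `T_SS` matches the mean and variance of a
#' chi-square with `d` degrees of freedom, and the p value is its upper tail.
#'
#' @param statistic Test statistic.
#' @param raw_weights Raw eigenvalues of `U Gamma` (length `d`).
#' @return A one-row tibble as in [pvalue_eigen()].
#' @export
pvalue_ss <- function(statistic, raw_weights) {
  d <- length(raw_weights)
  tr1 <- sum(raw_weights)
  tr2 <- sum(raw_weights^2)
  if (tr2 <= 0) stop("tr((U Gamma)^2) is zero: degenerate weights",
                     call. = FALSE)
  a <- sqrt(d / tr2)
  b <- sqrt(d * tr1^2 / tr2)
  t_ss <- a * statistic + d - b
  tibble::tibble(procedure = "SS", statistic = t_ss, df = d,
                 p_value = pchisq(t_ss, df = d, lower.tail = FALSE))
}

#' Scaled F p value
#'
#' Approximates the weighted chi-square mixture by `s * F(df1, df2)`,
#' matching the first three moments; the scaling and both degrees of freedom
#' are functions of the power sums `sum(l)`, `sum(l^2)`, `sum(l^3)` of the
#' eigenvalue weights. When the third-moment match degenerates (the mixture
#' is exactly chi-square, where the matching second denominator vanishes),
#' the two-moment scaled chi-square is used, which is then exact.
#'
#' @inheritParams pvalue_ss
#' @return A one-row tibble as in [pvalue_eigen()].
#' @export
pvalue_sf <- function(statistic, raw_weights) {
  d <- length(raw_weights)
  c1 <- sum(raw_weights)
  c2 <- sum(raw_weights^2)
  c3 <- sum(raw_weights^3)
  if (c1 <= 0 || c2 <= 0) stop("degenerate weights", call. = FALSE)
  mu1 <- c1
  mu2 <- 2 * c2 + c1^2              # raw second moment
  mu3 <- 8 * c3 + 6 * c1 * c2 + c1^3
  R2 <- mu2 / mu1^2
  R3 <- mu3 / (mu1 * mu2)
  den <- 2 * R2 - R3 - 1
  if (den <= 1e-10) {
    # exact chi-square limit of the F approximation (df2 -> infinity)
    s <- c2 / c1
    df1 <- c1^2 / c2
    p <- pchisq(statistic / s, df = df1, lower.tail = FALSE)
    return(tibble::tibble(procedure = "SF", statistic = statistic, df = d,
                          p_value = p))
  }
  x <- 4 * (R2 - R3) / den
  df2 <- x + 2
  Acoef <- R2 * (x - 2) / x
  df1 <- 2 / (Acoef - 1)
  if (!is.finite(df1) || !is.finite(df2) || df1 <= 0 || df2 <= 0) {
    stop(sprintf(paste0("scaled F approximation degenerate: df1 = %.4g, ",
                        "df2 = %.4g (power sums %.4g, %.4g, %.4g)"),
                 df1, df2, c1, c2, c3), call. = FALSE)
  }
  s <- mu1 * (df2 - 2) / df2
  p <- pf(statistic / s, df1 = df1, df2 = df2, lower.tail = FALSE)
  tibble::tibble(procedure = "SF", statistic = statistic, df = d,
                 p_value = p)
}

method_catalog <- function(d) {
  m <- list(
    list(label = "ALL", method = "ALL", nblocks = NULL),
    list(label = "pEBA2", method = "pEBA", nblocks = 2L),
    list(label = "pEBA4", method = "pEBA", nblocks = 4L),
    list(label = "pEBA6", method = "pEBA", nblocks = 6L),
    list(label = "pEBAdf", method = "pEBAdf", nblocks = NULL),
    list(label = "pOLS2", method = "pOLS2", nblocks = NULL),
    list(label = "SB", method = "SB", nblocks = NULL),
    list(label = "SS", method = "SS", nblocks = NULL),
    list(label = "SF", method = "SF", nblocks = NULL)
  )
  keep <- vapply(m, function(mm) is.null(mm$nblocks) || mm$nblocks <= d,
                 logical(1))
  if (!all(keep)) {
    warning("skipping block methods with more blocks than d = ", d,
            call. = FALSE)
  }
  m[keep]
}

robustified_pvalue <- function(entry, statistic, raw_weights) {
  if (entry$method == "SS") return(pvalue_ss(statistic, raw_weights))
  if (entry$method == "SF") return(pvalue_sf(statistic, raw_weights))
  pvalue_eigen(statistic, raw_weights, entry$method, entry$nblocks)
}

test_label <- function(method_label, base, gamma_variant) {
  lab <- method_label
  if (base == "RLS") lab <- paste0(lab, "_RLS")
  if (gamma_variant %in% c("unbiased", "UG")) lab <- paste0(lab, "_UG")
  lab
}

#' All goodness-of-fit tests for a fitted factor model
#'
#' Computes the two normal-theory tests (ML, RLS) and the full battery of
#' robustified tests: nine procedures (`ALL`, `pEBA` with 2, 4, 6 and `d`
#' blocks, `pOLS2`, `SB`, `SS`, `SF`), each crossed with base statistic
#' (`T_ML` or `T_RLS`) and `Gamma` estimator (biased or unbiased, the latter
#' tagged `_UG`), 38 results in total. Labels follow the
#' subscript/superscript notation flattened to ASCII, e.g. `pEBA4_RLS_UG`.
#'
#' @param fit A converged [cfa_fit][fit_ntml].
#' @param data Data frame or matrix of raw observations (needed for
#'   `Gamma`); for multi-group fits either a list of per-group matrices or a
#'   data frame with the `group` column named in `group`.
#' @param group Optional grouping column name.
#' @param bases Character subset of `c("ML", "RLS")`.
#' @param gamma_variants Character subset of `c("biased", "unbiased")`.
#' @return A tibble with columns `procedure`, `base`, `gamma_variant`,
#'   `statistic`, `df`, `p_value`; the normal-theory rows have
#'   `gamma_variant = NA`.
#' @export
gof_tests <- function(fit, data, group = NULL,
                      bases = c("ML", "RLS"),
                      gamma_variants = c("biased", "unbiased")) {
  X_list <- split_groups(data, group, fit$spec$G)
  um <- if (length(gamma_variants)) u_matrix(fit)
  stats <- list(ML = t_ml(fit), RLS = t_rls(fit))
  d <- fit$df

  rows <- list(
    tibble::tibble(procedure = "ML", base = "ML", gamma_variant = NA_character_,
                   statistic = stats$ML, df = d,
                   p_value = pchisq(stats$ML, d, lower.tail = FALSE)),
    tibble::tibble(procedure = "RLS", base = "RLS",
                   gamma_variant = NA_character_,
                   statistic = stats$RLS, df = d,
                   p_value = pchisq(stats$RLS, d, lower.tail = FALSE))
  )

  catalog <- method_catalog(d)
  for (variant in gamma_variants) {
    gam <- gamma_joint(X_list, variant)
    lam <- eigen_weights(um, gam)
    for (base in bases) {
      for (entry in catalog) {
        res <- robustified_pvalue(entry, stats[[base]], lam)
        res$procedure <- test_label(entry$label, base, variant)
        res$base <- base
        res$gamma_variant <- variant
        rows[[length(rows) + 1L]] <- res[, c("procedure", "base",
                                             "gamma_variant", "statistic",
                                             "df", "p_value")]
      }
    }
  }
  dplyr::bind_rows(rows)
}

split_groups <- function(data, group, G) {
  if (is.list(data) && !is.data.frame(data)) {
    stopifnot(length(data) == G)
    return(lapply(data, as.matrix))
  }
  data <- as.data.frame(data)
  if (is.null(group)) {
    if (G != 1) stop("multi-group model needs grouped data", call. = FALSE)
    return(list(as.matrix(data[vapply(data, is.numeric, logical(1))])))
  }
  gvals <- sort(unique(data[[group]]))
  stopifnot(length(gvals) == G)
  lapply(gvals, function(gv) {
    dg <- data[data[[group]] == gv, setdiff(names(data), group), drop = FALSE]
    as.matrix(dg[vapply(dg, is.numeric, logical(1))])
  })
}
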