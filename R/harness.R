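#' Condition grids for the Monte Carlo studies
#'
#' Builds the fully crossed condition grid of a study (sample sizes,
#' dimensions, group counts, distributions). `scale = "full"` reproduces the
#' published grids (84 conditions for study 1, 189 for study 2, 63 for the
#' goodness-of-fit power study, 189 for the invariance power study);
#' `scale = "reduced"` subsamples levels while preserving the crossing, for
#' desk-scale runs.
#'
#' @param study `"study1"`, `"study2"`, `"study3_gof"` or
#'   `"study3_invariance"`.
#' @param scale `"full"` or `"reduced"`.
#' @param reps Replications per condition.
#' @param seed Base seed; condition `i` uses `seed + i`.
#' @return A tibble of conditions with an `adequate` flag (`n/q >= 10`).
#' @export
build_study_grid <- function(study = c("study1", "study2", "study3_gof",
                                       "study3_invariance"),
                             scale = c("full", "reduced"),
                             reps = if (scale == "full") 2000L else 200L,
                             seed = 1L) {
  study <- match.arg(study)
  scale <- match.arg(scale)
  fams <- c("N", "VM1", "PL1", "IG1", "VM2", "PL2", "IG2")
  if (scale == "reduced") fams <- c("N", "VM2", "PL2")
  ns <- if (scale == "full") c(400L, 800L, 2000L) else c(400L, 2000L)
  if (study %in% c("study1", "study3_gof")) {
    ps <- if (study == "study1") c(15L, 30L, 60L, 100L) else c(15L, 30L, 60L)
    if (scale == "reduced") ps <- 15L
    grid <- expand.grid(n = ns, p = ps, family = fams, G = 1L,
                        stringsAsFactors = FALSE)
    q <- 2L * grid$p + 10L
  } else {
    ps <- if (scale == "full") c(5L, 10L, 20L) else c(5L, 10L)
    Gs <- if (scale == "full") c(2L, 4L, 8L) else 2L
    grid <- expand.grid(n = ns, p = ps, G = Gs, family = fams,
                        stringsAsFactors = FALSE)
    # q of the unconstrained model: G(p-1) loadings + G factor and Gp
    # residual variances
    q <- grid$G * (grid$p - 1L) + grid$G + grid$G * grid$p
  }
  tibble::tibble(
    study = study, p = grid$p, G = grid$G, n = grid$n,
    family = grid$family, reps = as.integer(reps),
    seed = seed + seq_len(nrow(grid)),
    adequate = grid$n / q >= 10
  )
}

parse_method_label <- function(label) {
  if (label %in% c("ML", "RLS")) {
    return(list(procedure = label, base = label, gamma = NA_character_,
                robustified = FALSE))
  }
  if (label == "SB_2001") {
    return(list(procedure = label, base = "ML", gamma = "biased",
                robustified = TRUE))
  }
  core <- label
  gamma <- "biased"
  base <- "ML"
  if (grepl("_UG$", core)) {
    gamma <- "unbiased"
    core <- sub("_UG$", "", core)
  }
  if (grepl("_RLS$", core)) {
    base <- "RLS"
    core <- sub("_RLS$", "", core)
  }
  valid <- c("ALL", "pEBA2", "pEBA4", "pEBA6", "pEBAdf", "pOLS2", "SB", "SS",
             "SF")
  if (!core %in% valid) {
    stop("unknown method label '", label, "'; valid cores are ",
         paste(c(valid, "ML", "RLS", "SB_2001"), collapse = ", "),
         " with optional _RLS and _UG suffixes", call. = FALSE)
  }
  list(procedure = label, base = base, gamma = gamma, robustified = TRUE)
}

#' Run one Monte Carlo condition
#'
#' Draws `reps` replications from the condition's population, fits the
#' analysis model(s), computes the requested test p values and returns
#' per-method rejection rates at the 5% level. Replications whose fits do
#' not converge (or produce Heywood cases) are discarded and counted; a
#' condition with more than 20% discarded replications is flagged invalid.
#'
#' @param cond A one-row condition (as produced by [build_study_grid()]), or
#'   a list with fields `study`, `p`, `G`, `n`, `family`, `reps`, `seed`.
#' @param methods Character vector of test labels (e.g. `"pEBA4_RLS"`,
#'   `"pEBAdf_UG"`, `"RLS"`, `"SB_2001"`).
#' @param ud_method `U_D` estimator for nested studies.
#' @param h Loading perturbation for the invariance power study.
#' @param alpha Significance level of the rejection decision.
#' @param keep_pvalues If `TRUE`, the per-replication p values are attached
#'   as an attribute `"pvalues"` (a reps x methods matrix).
#' @param pop_seed Seed of the once-drawn population loadings. The drawn
#'   loadings are part of the study design, so they default to a fixed
#'   scenario constant rather than following `cond$seed`, which drives the
#'   replication sampling.
#' @return A tibble of class `peba_mc` with one row per method: condition
#'   descriptors, `rejection_rate` (percent), `reps_used`, `discarded`,
#'   `valid`.
#' @export
run_condition <- function(cond, methods = c("pEBA4_RLS", "RLS"),
                          ud_method = c("2000", "2001"), h = 0.2,
                          alpha = 0.05, keep_pvalues = FALSE,
                          pop_seed = 1L) {
  ud_method <- match.arg(ud_method)
  cond <- as.list(cond)
  parsed <- lapply(methods, parse_method_label)
  bases <- unique(vapply(parsed, function(x) x$base, character(1)))
  gammas <- unique(stats::na.omit(vapply(parsed, function(x) x$gamma,
                                         character(1))))
  nested <- cond$study %in% c("study2", "study3_invariance")
  pop <- build_study_population(cond$study, cond$p, G = cond$G,
                                seed = pop_seed, h = h)
  generator <- prepare_generator(pop, cond$family)

  # warn once per condition (not per replication) about skipped block methods
  d_cond <- if (nested) (cond$G - 1) * (cond$p - 1) else pop$spec$df
  blocks <- c(pEBA2 = 2, pEBA4 = 4, pEBA6 = 6)
  for (nm in names(blocks)) {
    if (blocks[[nm]] > d_cond && any(startsWith(methods, nm))) {
      warning("method ", nm, " skipped: more blocks than d = ", d_cond,
              call. = FALSE)
    }
  }

  set.seed(cond$seed)
  pmat <- matrix(NA_real_, cond$reps, length(methods),
                 dimnames = list(NULL, methods))
  discarded <- 0L
  for (r in seq_len(cond$reps)) {
    X_list <- generator(cond$n)
    res <- tryCatch(
      suppressWarnings(
        replication_tests(pop, X_list, nested, bases, gammas, ud_method,
                          needs_sb2001 = "SB_2001" %in% methods)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) {
      discarded <- discarded + 1L
      next
    }
    pmat[r, ] <- res$p_value[match(methods, res$procedure)]
  }
  used <- cond$reps - discarded
  rr <- 100 * colMeans(pmat < alpha, na.rm = TRUE)
  out <- tibble::tibble(
    study = cond$study, p = cond$p, G = cond$G, n = cond$n,
    family = cond$family, method = methods,
    rejection_rate = as.numeric(rr),
    reps_used = used, discarded = discarded,
    valid = discarded <= 0.2 * cond$reps
  )
  class(out) <- c("peba_mc", class(out))
  if (keep_pvalues) attr(out, "pvalues") <- pmat
  out
}

replication_tests <- function(pop, X_list, nested, bases, gammas, ud_method,
                              needs_sb2001 = FALSE) {
  if (!nested) {
    S <- sample_cov_biased(X_list[[1]])
    fit <- fit_ntml(list(S), list(nrow(X_list[[1]])), pop$spec)
    if (!fit$converged || fit$heywood) stop("discard")
    return(gof_tests(fit, X_list, bases = bases, gamma_variants = gammas))
  }
  pair <- pop$pair
  S_list <- lapply(X_list, sample_cov_biased)
  N_list <- lapply(X_list, nrow)
  fit1 <- fit_m1_groupwise(S_list, N_list, pair)
  if (!fit1$converged || fit1$heywood) stop("discard")
  fit0 <- fit_ntml(S_list, N_list, pair$m0,
                   start = m0_start_from_m1(fit1, pair))
  if (!fit0$converged || fit0$heywood) stop("discard")
  res <- nested_tests(fit0, fit1, X_list, A = pair$A, ud_method = ud_method,
                      bases = bases, gamma_variants = gammas)
  if (needs_sb2001 && ud_method != "2001") {
    extra <- nested_tests(fit0, fit1, X_list, A = pair$A, ud_method = "2001",
                          bases = "ML", gamma_variants = "biased")
    res <- dplyr::bind_rows(res, extra[extra$procedure == "SB_2001", ])
  }
  res
}

#' Aggregate rejection rates into the evaluation metrics
#'
#' Given per-condition rejection rates (in percent) of one method, computes
#' `RMSE = sqrt(mean((RR - 5)^2))`, `MAD = mean(|RR - 5|)`, and the Bradley
#' band proportions: `ARR` (percent of RRs in the inclusive band
#' `[2.5, 7.5]`), `B2.5` (below) and `A7.5` (above). `ARR + B2.5 + A7.5`
#' equals 100.
#'
#' @param rr Numeric vector of rejection rates in percent.
#' @param nominal Nominal rejection rate (percent).
#' @return A one-row tibble with columns `RMSE`, `MAD`, `ARR`, `B2.5`,
#'   `A7.5`, `n_conditions`.
#' @examples
#' aggregate_metrics(c(3, 7))  # RMSE = MAD = 2, ARR = 100
#' @export
aggregate_metrics <- function(rr, nominal = 5) {
  if (length(rr) == 0) stop("no rejection rates to aggregate", call. = FALSE)
  tibble::tibble(
    RMSE = sqrt(mean((rr - nominal)^2)),
    MAD = mean(abs(rr - nominal)),
    ARR = 100 * mean(rr >= 2.5 & rr <= 7.5),
    B2.5 = 100 * mean(rr < 2.5),
    A7.5 = 100 * mean(rr > 7.5),
    n_conditions = length(rr)
  )
}
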