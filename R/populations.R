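#' Population models for the Monte Carlo studies
#'
#' Builds the data-generating population for each study design:
#'
#' * `"study1"` — single-group five-factor model with `p/5` indicators per
#'   factor, unit factor and residual variances, loadings drawn once (seeded)
#'   from `U[0.5, 1.5]`, and the six interfactor correlations
#'   `-0.3, -0.2, 0, 0.1, 0.2, 0.3` assigned cyclically to the ten factor
#'   pairs. Loadings are nested across dimensions: the `p = 15` loadings are
#'   the leading entries of the `p = 30` loadings, and so on.
#' * `"study2"` — one-factor model with invariant loadings in `G` groups
#'   (unit factor and residual variances; loadings nested across `p`).
#' * `"study3_gof"` — the study-1 model plus an orthogonal unit-variance
#'   method factor loading with alternating signs `+lambda_m, -lambda_m, ...`
#'   on the odd-numbered indicators of the first factor;
#'   `lambda_m = 0.78, 0.43, 0.32` for `p = 15, 30, 60`. The analysis model
#'   omits the method factor, so fitting the five-factor specification to
#'   this population probes power.
#' * `"study3_invariance"` — the study-2 model with loadings perturbed in
#'   groups `2..G`: loading `i` of group `g > 1` is shifted by
#'   `h * (-1)^i`, breaking weak invariance by `h` (default 0.2).
#'
#' @param study One of `"study1"`, `"study2"`, `"study3_gof"`,
#'   `"study3_invariance"`.
#' @param p Number of observed variables (study 1/3gof: divisible by 5 and at
#'   most 100; study 2/3inv: at most 20).
#' @param G Number of groups (study 2/3inv).
#' @param seed Seed controlling the loading draw.
#' @param h Loading perturbation for `"study3_invariance"`.
#' @return A `population_model`: list with the per-group `sigma` (list),
#'   `lambda`, `phi`, `psi`, the analysis `spec`, and bookkeeping fields.
#' @export
build_study_population <- function(study = c("study1", "study2", "study3_gof",
                                             "study3_invariance"),
                                   p, G = 1, seed = 1, h = 0.2) {
  study <- match.arg(study)
  out <- switch(study,
    study1 = population_five_factor(p, seed, method_loading = 0),
    study3_gof = population_five_factor(p, seed,
                                        method_loading = method_lambda(p)),
    study2 = population_invariance(p, G, seed, h = 0),
    study3_invariance = population_invariance(p, G, seed, h = h)
  )
  out$study <- study
  out$seed <- seed
  class(out) <- "population_model"
  out
}

method_lambda <- function(p) {
  lam <- c(`15` = 0.78, `30` = 0.43, `60` = 0.32)[as.character(p)]
  if (is.na(lam)) {
    stop("method-factor design is defined for p = 15, 30, 60", call. = FALSE)
  }
  unname(lam)
}

# Loadings for the five-factor family, nested across dimensions: a master
# vector of 20 seeded U[0.5, 1.5] draws per factor, truncated to p/5.
population_five_factor <- function(p, seed, method_loading = 0) {
  if (p %% 5 != 0 || p > 100) {
    stop("five-factor design needs p divisible by 5 and at most 100",
         call. = FALSE)
  }
  m <- p / 5
  master <- with_preserved_seed(seed, matrix(runif(100, 0.5, 1.5), 20, 5))
  lambda <- matrix(0, p, 5)
  for (j in 1:5) lambda[(j - 1) * m + seq_len(m), j] <- master[seq_len(m), j]
  phi <- diag(5)
  vals <- c(-0.3, -0.2, 0, 0.1, 0.2, 0.3)
  pairs <- which(lower.tri(phi), arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    phi[pairs[k, 1], pairs[k, 2]] <- vals[(k - 1) %% 6 + 1]
    phi[pairs[k, 2], pairs[k, 1]] <- phi[pairs[k, 1], pairs[k, 2]]
  }
  psi <- diag(p)
  sigma <- lambda %*% phi %*% t(lambda) + psi
  misspec <- NULL
  if (method_loading > 0) {
    idx <- seq(1, m, by = 2)                      # odd indicators of factor 1
    mvec <- numeric(p)
    mvec[idx] <- method_loading * (-1)^(seq_along(idx) - 1)
    sigma <- sigma + tcrossprod(mvec)
    misspec <- list(type = "method_factor", loading = method_loading,
                    vector = mvec)
  }
  list(p = p, G = 1, lambda = lambda, phi = phi, psi = psi,
       sigma = list(sigma), spec = study_gof_spec(p), misspec = misspec)
}

population_invariance <- function(p, G, seed, h = 0) {
  if (!p %in% c(5, 10, 20) && (p < 3 || p > 100)) {
    stop("invariance design needs 3 <= p <= 100", call. = FALSE)
  }
  master <- with_preserved_seed(seed, runif(20, 0.5, 1.5))
  if (p > 20) master <- with_preserved_seed(seed, runif(p, 0.5, 1.5))
  lambda_base <- master[seq_len(p)]
  lambda_g <- lapply(seq_len(G), function(g) {
    lam <- lambda_base
    if (h != 0 && g > 1) lam <- lam + h * (-1)^seq_len(p)
    matrix(lam, p, 1)
  })
  psi <- diag(p)
  sigma <- lapply(lambda_g, function(L) L %*% t(L) + psi)
  pair <- make_invariance_pair(p, max(G, 2))
  list(p = p, G = G, lambda = lambda_g, phi = diag(1), psi = psi,
       sigma = sigma, spec = pair$m0, pair = pair,
       misspec = if (h != 0) list(type = "loading_perturbation", h = h))
}

# Evaluate an expression under a given RNG seed without disturbing the
# caller's RNG stream.
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Draw a sample from a population under a distribution condition
#'
#' Dispatches to the normal, Vale-Maurelli, independent-generator or
#' piecewise-linear sampler with the condition's marginal targets:
#' `"N"` (normal), `"VM1"/"IG1"/"PL1"` (skewness 2, excess kurtosis 7),
#' `"VM2"/"IG2"/"PL2"` (skewness 3, excess kurtosis 21). Multi-group
#' populations are sampled independently per group. For replication loops,
#' [prepare_generator()] performs the per-condition calibration work
#' (Fleishman solves, piecewise-linear calibration, intermediate
#' correlations) once and returns a sampler closure.
#'
#' @param pop A [population_model][build_study_population].
#' @param family Distribution label (`"N"`, `"VM1"`, `"VM2"`, `"IG1"`,
#'   `"IG2"`, `"PL1"`, `"PL2"`).
#' @param n Per-group sample size.
#' @param seed Optional seed.
#' @param generator Optional prepared sampler from [prepare_generator()].
#' @return A list of per-group `n x p` matrices.
#' @export
draw_sample <- function(pop, family, n, seed = NULL, generator = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(generator)) generator <- prepare_generator(pop, family)
  generator(n)
}

#' @rdname draw_sample
#' @export
prepare_generator <- function(pop, family) {
  targets <- family_targets(family)
  group_gens <- lapply(seq_len(pop$G), function(g) {
    sig <- pop$sigma[[g]]
    sds <- sqrt(diag(sig))
    p <- pop$p
    if (targets$family == "N") {
      ch <- chol(stats::cov2cor(sig))
      return(function(n) {
        (matrix(rnorm(n * p), n, p) %*% ch) %*% diag(sds, p)
      })
    }
    if (targets$family == "IG") {
      lam <- if (is.list(pop$lambda)) pop$lambda[[g]] else pop$lambda
      extra <- if (!is.null(pop$misspec) &&
                     identical(pop$misspec$type, "method_factor")) {
        cbind(lam, pop$misspec$vector)
      } else lam
      phi_aug <- diag(ncol(extra))
      phi_aug[seq_len(ncol(pop$phi)), seq_len(ncol(pop$phi))] <- pop$phi
      return(ig_prepare(extra, phi_aug, diag(pop$psi), targets$skew,
                        targets$exkurt))
    }
    # VM and PL: marginal transform of a normal with solved intermediate
    # correlations
    R <- stats::cov2cor(sig)
    vals <- unique(R[lower.tri(R)])
    if (targets$family == "VM") {
      cf <- fleishman_coefficients(targets$skew, targets$exkurt)
      solved <- vapply(vals, function(r) vm_intermediate_corr(r, cf),
                       numeric(1))
      transform <- function(z) fleishman_transform(z, cf)
    } else {
      calib <- pl_calib_cache_get(targets$skew, targets$exkurt)
      solved <- vapply(vals, function(r) pl_intermediate_corr(r, calib),
                       numeric(1))
      transform <- function(z) pl_transform(z, calib)
    }
    Rz <- diag(p)
    for (k in seq_along(vals)) {
      Rz[lower.tri(Rz)][R[lower.tri(R)] == vals[k]] <- solved[k]
    }
    Rz[upper.tri(Rz)] <- t(Rz)[upper.tri(Rz)]
    ch <- tryCatch(chol(Rz), error = function(e) NULL)
    if (is.null(ch)) {
      stop("intermediate correlation matrix is not positive definite",
           call. = FALSE)
    }
    function(n) {
      Z <- matrix(rnorm(n * p), n, p) %*% ch
      matrix(transform(as.vector(Z)), n, p) %*% diag(sds, p)
    }
  })
  function(n) lapply(group_gens, function(f) f(n))
}

# Calibrations depend only on the marginal targets; cache them per target.
pl_calib_env <- new.env(parent = emptyenv())
pl_calib_cache_get <- function(skew, exkurt) {
  key <- paste(skew, exkurt)
  if (is.null(pl_calib_env[[key]])) {
    pl_calib_env[[key]] <- pl_calibrate(skew, exkurt)
  }
  pl_calib_env[[key]]
}

family_targets <- function(family) {
  table <- list(
    N   = list(family = "N", skew = 0, exkurt = 0),
    VM1 = list(family = "VM", skew = 2, exkurt = 7),
    VM2 = list(family = "VM", skew = 3, exkurt = 21),
    IG1 = list(family = "IG", skew = 2, exkurt = 7),
    IG2 = list(family = "IG", skew = 3, exkurt = 21),
    PL1 = list(family = "PL", skew = 2, exkurt = 7),
    PL2 = list(family = "PL", skew = 3, exkurt = 21)
  )
  out <- table[[family]]
  if (is.null(out)) stop("unknown distribution family: ", family,
                         call. = FALSE)
  out
}
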