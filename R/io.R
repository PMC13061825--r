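#' Read a run configuration
#'
#' Parses a YAML configuration describing an analysis run: `mode`
#' (`"gof"`, `"nested"` or `"study"`), data/model locations or a study
#' descriptor, the method list, `Gamma` variant, `U_D` method, and seed.
#' Unknown method labels are rejected with the list of valid labels;
#' defaults follow the recommended procedures (`pEBA4_RLS` for
#' goodness-of-fit, `pEBAdf_UG` for nested comparisons).
#'
#' @param path Path to a YAML file.
#' @return A validated named list of class `run_config`.
#' @export
parse_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$mode) || !cfg$mode %in% c("gof", "nested", "study")) {
    stop("config field 'mode' must be one of gof, nested, study",
         call. = FALSE)
  }
  if (is.null(cfg$methods)) {
    cfg$methods <- if (cfg$mode == "nested") "pEBAdf_UG" else "pEBA4_RLS"
  }
  lapply(cfg$methods, parse_method_label)  # validates, errors on unknown
  if (!is.null(cfg$ud_method)) {
    cfg$ud_method <- as.character(cfg$ud_method)
    stopifnot(cfg$ud_method %in% c("2000", "2001"))
  } else if (cfg$mode == "nested") {
    cfg$ud_method <- "2000"
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = c("run_config", "list"))
}

#' Build a model specification from a config mapping
#'
#' Converts a `factors:` mapping (factor name to indicator column names) into
#' a [cfa_spec][new_cfa_spec] via [simple_cfa_spec()], and returns the
#' indicator column order expected by the fitted model.
#'
#' @param model A named list mapping factors to indicator names, or a path to
#'   a YAML file with a top-level `factors:` mapping.
#' @return List with `spec` and `variables`.
#' @export
read_model_config <- function(model) {
  if (is.character(model) && length(model) == 1) {
    model <- yaml::read_yaml(model)$factors
  }
  vars <- unlist(model, use.names = FALSE)
  if (anyDuplicated(vars)) {
    stop("each indicator may load on one factor only", call. = FALSE)
  }
  factor_of <- rep(seq_along(model), lengths(model))
  list(spec = simple_cfa_spec(factor_of), variables = vars)
}

#' Read raw observations or a covariance matrix from delimited text
#'
#' `read_observations()` reads a delimited text file with a header row (one
#' row per observation, optional group column) into a tibble ready for
#' [fit_cfa()]. `read_covariance()` reads a square covariance matrix (with
#' or without header) for the covariance-input mode of [fit_ntml()].
#'
#' @param path File path.
#' @param sep Field separator; `""` (default) means any whitespace.
#' @return A tibble of observations, or a list with elements `S` (matrix)
#'   and `N` for `read_covariance`.
#' @export
read_observations <- function(path, sep = "") {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = sep,
                                      check.names = FALSE))
}

#' @rdname read_observations
#' @param n Sample size that produced the covariance matrix.
#' @export
read_covariance <- function(path, n, sep = "") {
  first <- readLines(path, n = 1L)
  has_header <- any(is.na(suppressWarnings(
    as.numeric(strsplit(trimws(first), "[,;[:space:]]+")[[1]])
  )))
  S <- as.matrix(utils::read.table(path, header = has_header, sep = sep))
  dimnames(S) <- NULL
  if (nrow(S) != ncol(S)) stop("covariance file is not square", call. = FALSE)
  list(S = (S + t(S)) / 2, N = n)
}

#' Write and read test results
#'
#' Results are stored as tab-separated text with full (17 significant digit)
#' precision so that p values round-trip bit-faithfully. Metadata (seed,
#' grid description, discard counts) is written as `# key: value` header
#' lines and recovered on read.
#'
#' @param results A data frame of results.
#' @param path Output path.
#' @param metadata Optional named list written as header comments.
#' @return `write_results` returns `path` invisibly; `read_results` returns a
#'   tibble with the metadata in `attr(, "metadata")`.
#' @export
write_results <- function(results, path, metadata = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(metadata)) {
    for (nm in names(metadata)) {
      writeLines(sprintf("# %s: %s", nm,
                         paste(format(metadata[[nm]], digits = 17),
                               collapse = ",")), con)
    }
  }
  df <- as.data.frame(results)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  metadata <- list()
  for (ln in lines[meta_lines]) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    metadata[[key]] <- sub("^[^:]*:\\s*", "", kv)
  }
  body <- if (length(meta_lines)) lines[-meta_lines] else lines
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- tibble::as_tibble(df)
  attr(out, "metadata") <- metadata
  out
}

#' Deterministic small fixtures for regression testing
#'
#' Generates a bundle of small two-group one-factor datasets (`p = 5`,
#' `n = 200` per group) under the four distribution families, with the
#' invariant population of the invariance design. Identical seeds reproduce
#' identical data.
#'
#' @param seed Integer seed.
#' @return Named list of data frames (columns `x1..x5`, `group`), one per
#'   family, plus the `population_model` used.
#' @export
make_fixtures <- function(seed = 1L) {
  pop <- build_study_population("study2", p = 5, G = 2, seed = seed)
  fams <- c("N", "VM1", "IG1", "PL1")
  out <- lapply(fams, function(fam) {
    X <- draw_sample(pop, fam, n = 200, seed = seed + match(fam, fams))
    df <- as.data.frame(do.call(rbind, X))
    names(df) <- paste0("x", 1:5)
    df$group <- rep(seq_along(X), each = 200)
    tibble::as_tibble(df)
  })
  names(out) <- fams
  out$population <- pop
  out
}
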