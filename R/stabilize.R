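#' Eigenvalue stabilizers
#'
#' Transforms the unstable raw eigenvalue estimates of `U Gamma` into the
#' stabilized weight vector used in the mixture p value:
#'
#' * `ALL` — identity (raw weights used as-is);
#' * `SB` — every entry replaced by the grand mean (the mixture
#'   representation of Satorra-Bentler mean scaling);
#' * `EBAx` — means of `x` equally sized blocks of consecutive eigenvalues;
#' * `pEBAx` — elementwise average of the `EBAx` vector and the grand mean;
#' * `pEBAdf` — `pEBA` with `d` singleton blocks:
#'   `(raw + mean(raw)) / 2`;
#' * `pOLS2` — fitted values of the least-squares line of the sorted
#'   eigenvalues on their index, averaged elementwise with the grand mean and
#'   floored at a small positive constant.
#'
#' All methods except `ALL` (trivially) preserve the mean of the raw vector;
#' `pOLS2` preserves it before flooring. When `d` is not divisible by the
#' number of blocks, blocks are as equal as possible with the larger blocks
#' taking the smallest eigenvalues.
#'
#' @param raw Numeric vector of raw eigenvalues sorted in increasing order.
#' @param method One of `"ALL"`, `"SB"`, `"EBA"`, `"pEBA"`, `"pEBAdf"`,
#'   `"pOLS2"`.
#' @param nblocks Number of blocks for `EBA`/`pEBA`.
#' @return Stabilized weight vector of the same length.
#' @examples
#' stabilize(c(1, 2, 3, 4), "pEBA", nblocks = 2)  # 2.0 2.0 3.0 3.0
#' @export
stabilize <- function(raw,
                      method = c("ALL", "SB", "EBA", "pEBA", "pEBAdf",
                                 "pOLS2"),
                      nblocks = NULL) {
  method <- match.arg(method)
  d <- length(raw)
  if (d < 1) stop("empty weight vector", call. = FALSE)
  if (is.unsorted(raw, strictly = FALSE)) {
    stop("'raw' must be sorted in increasing order", call. = FALSE)
  }
  grand <- mean(raw)
  switch(method,
    ALL = raw,
    SB = rep(grand, d),
    EBA = block_means(raw, check_nblocks(nblocks, d)),
    pEBA = (block_means(raw, check_nblocks(nblocks, d)) + grand) / 2,
    pEBAdf = (raw + grand) / 2,
    pOLS2 = {
      idx <- seq_len(d)
      fitted <- if (d == 1) grand else {
        b <- sum((idx - mean(idx)) * (raw - grand)) / sum((idx - mean(idx))^2)
        grand + b * (idx - mean(idx))
      }
      pmax((fitted + grand) / 2, 1e-8)
    }
  )
}

check_nblocks <- function(nblocks, d) {
  if (is.null(nblocks) || length(nblocks) != 1 || !is.finite(nblocks) ||
      nblocks < 1 || nblocks > d || nblocks != round(nblocks)) {
    stop("'nblocks' must be an integer in 1..", d, call. = FALSE)
  }
  as.integer(nblocks)
}

# Partition d sorted values into x consecutive blocks, as equal as possible;
# the remainder is allocated to the leading blocks (smallest eigenvalues),
# and each value is replaced by its block mean.
block_means <- function(raw, x) {
  d <- length(raw)
  base <- d %/% x
  rem <- d %% x
  sizes <- rep(base, x) + c(rep(1L, rem), rep(0L, x - rem))
  f <- rep(seq_len(x), sizes)
  means <- vapply(split(raw, f), mean, numeric(1))
  unname(rep(means, sizes))
}
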