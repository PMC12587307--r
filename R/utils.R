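# Internal helpers shared across the package.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores (or removes) the global \code{.Random.seed} afterwards, so seeded
#' package functions do not disturb the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

#' Derive a per-stage seed from a single pipeline seed
#'
#' Deterministic fan-out so each pipeline stage is independently
#' reproducible: the stage name is hashed to a small integer offset.
#' Result stays below 2^31.
#' @param seed integer master seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 131 + h) %% (2^31 - 1))
}

# Validate a binary indicator matrix; returns it as a double matrix with
# rownames preserved (ids are required by the stability machinery).
check_binary_matrix <- function(X, arg = "X") {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) stop(sprintf("`%s` must be a matrix of 0/1 indicators", arg))
  storage.mode(X) <- "double"
  if (anyNA(X) || !all(X == 0 | X == 1)) {
    bad <- which(is.na(X) | (X != 0 & X != 1), arr.ind = TRUE)[1L, , drop = TRUE]
    stop(sprintf("`%s` contains a non-binary entry at row %d, column %d",
                 arg, bad[["row"]], bad[["col"]]))
  }
  X
}

# Row-wise log-sum-exp of a matrix (max.col keeps it O(nK) in C).
row_logsumexp <- function(L) {
  m <- L[cbind(seq_len(nrow(L)), max.col(L, ties.method = "first"))]
  m + log(rowSums(exp(L - m)))
}

# Truncated-normal sampler on [lower, Inf) via inverse CDF; vectorised and
# exact (no rejection), so the draw count per subject is fixed.
rtruncnorm_left <- function(n, mean, sd, lower = 0) {
  p_lo <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n)
  q <- stats::qnorm(p_lo + u * (1 - p_lo), mean, sd)
  pmax(q, lower)  # guard against qnorm(1) overflow at extreme truncation
}
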