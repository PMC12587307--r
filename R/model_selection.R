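# Model selection: score candidate class numbers K = 1..K_max with BIC, ICL
# and the average silhouette width, and extract the candidate set that moves
# on to bootstrap stability assessment.

#' BIC and ICL of a fitted latent-class model
#'
#' BIC \eqn{= -2\ell + p\log n} with \eqn{p = (K-1) + KJ} free parameters;
#' ICL is the entropy-augmented form \eqn{ICL = BIC + 2 EN} with
#' \eqn{EN = -\sum_{ik} \tau_{ik}\log\tau_{ik}}, which penalises poorly
#' separated classes (ICL >= BIC always). Lower is better for both.
#'
#' @param fitted an `lca_fit`.
#' @param n number of observations (defaults to the fitted n).
#' @return named numeric: `BIC`, `ICL`, `EN`, `p`.
#' @export
information_criteria <- function(fitted, n = fitted$n) {
  if (!is.numeric(n) || n <= 0) stop("`n` must be positive")
  K <- fitted$params$K
  J <- fitted$J
  p <- (K - 1) + K * J
  if (!is.null(fitted$constrained_items)) {
    p <- p - (K - 1) * length(fitted$constrained_items)
  }
  tau <- fitted$tau
  en <- -sum(ifelse(tau > 0, tau * log(tau), 0))
  bic <- -2 * fitted$loglik + p * log(n)
  c(BIC = bic, ICL = bic + 2 * en, EN = en, p = p)
}

# Pairwise Jaccard distance matrix on binary rows: d = 1 - |x & y| / |x | y|.
# stats::dist(method = "binary") implements exactly this for 0/1 data.
jaccard_dist <- function(X) {
  X <- check_binary_matrix(X)
  if (any(rowSums(X) == 0)) {
    stop("Jaccard distance undefined for all-zero rows; drop the no-comorbidity stratum first")
  }
  stats::dist(X, method = "binary")
}

#' Average silhouette width of a partition under Jaccard distance
#'
#' For subject i with within-cluster mean distance a(i) and smallest
#' other-cluster mean distance b(i), \eqn{s(i) = (b(i)-a(i))/\max(a(i),b(i))}
#' (0 when both are 0, and 0 for members of singleton clusters, the
#' Rousseeuw convention); the ASW is the mean of s(i) and lies in [-1, 1].
#' Comorbidity vectors are binary and asymmetric, so the Jaccard distance
#' \eqn{1 - |x \wedge y|/|x \vee y|} is used.
#'
#' @param X binary matrix (no all-zero rows).
#' @param partition factor of cluster memberships for the rows of `X`.
#' @param dist optional pre-computed distance (`dist` or square matrix) to
#'   amortise the O(n^2) cost across several calls.
#' @return the ASW, or `NA_real_` when the partition has a single
#'   (non-empty) cluster, for which the silhouette is undefined.
#' @export
silhouette_asw <- function(X, partition, dist = NULL) {
  partition <- droplevels(as.factor(partition))
  if (nlevels(partition) < 2L) return(NA_real_)
  if (is.null(dist)) dist <- jaccard_dist(X)
  D <- as.matrix(dist)
  if (length(partition) != nrow(D)) stop("partition length must match the number of rows")
  G <- stats::model.matrix(~ 0 + partition)       # n x K indicator
  sizes <- colSums(G)
  S <- D %*% G                                     # total distance to each cluster
  own <- as.integer(partition)
  idx <- cbind(seq_along(own), own)
  a <- S[idx] / pmax(sizes[own] - 1, 1)
  Sb <- S / matrix(sizes, nrow(D), length(sizes), byrow = TRUE)
  Sb[idx] <- Inf
  b <- do.call(pmin, lapply(seq_len(ncol(Sb)), function(j) Sb[, j]))
  s <- ifelse(sizes[own] == 1, 0,
              ifelse(pmax(a, b) == 0, 0, (b - a) / pmax(a, b)))
  mean(s)
}

#' Score latent-class models across K = 1..K_max
#'
#' Fits each K with [fit_lca()] (per-K seeds derived from `seed`), computes
#' log-likelihood, parameter count, BIC, ICL, entropy and the ASW of the MAP
#' partition (undefined at K = 1). A K whose fit fails is kept as a `failed`
#' row rather than aborting the scan.
#'
#' @param X binary matrix of comorbid subjects.
#' @param k_max largest K to scan (default 10, chosen for parsimony and
#'   clinical interpretability).
#' @param fit_opts list of options passed to [fit_lca()] (`n_restarts`,
#'   `tol`, `max_iter`).
#' @param seed integer scan seed.
#' @param keep_fits attach the fitted models as the `fits` attribute?
#' @return `data.frame` of class `model_metrics` with one row per K:
#'   `K, loglik, p, BIC, ICL, EN, ASW, converged, failed`.
#' @export
scan_models <- function(X, k_max = 10, fit_opts = list(), seed = NULL,
                        keep_fits = FALSE) {
  X <- check_binary_matrix(X)
  if (nrow(X) <= k_max) stop("need more subjects than k_max")
  D <- jaccard_dist(X)
  rows <- vector("list", k_max)
  fits <- vector("list", k_max)
  for (K in seq_len(k_max)) {
    res <- tryCatch({
      fit <- do.call(fit_lca, c(list(X = X, K = K,
                                     seed = if (is.null(seed)) NULL else stage_seed(seed, paste0("scan_K", K))),
                                fit_opts))
      ic <- information_criteria(fit)
      asw <- if (K == 1L) NA_real_ else silhouette_asw(X, map_assign(fit), dist = D)
      if (keep_fits) fits[[K]] <- fit
      data.frame(K = K, loglik = fit$loglik, p = ic[["p"]], BIC = ic[["BIC"]],
                 ICL = ic[["ICL"]], EN = ic[["EN"]], ASW = asw,
                 converged = fit$converged, failed = FALSE)
    }, error = function(e) {
      warning(sprintf("fit failed for K = %d: %s", K, conditionMessage(e)))
      data.frame(K = K, loglik = NA_real_, p = NA_real_, BIC = NA_real_,
                 ICL = NA_real_, EN = NA_real_, ASW = NA_real_,
                 converged = FALSE, failed = TRUE)
    })
    rows[[K]] <- res
  }
  out <- do.call(rbind, rows)
  class(out) <- c("model_metrics", "data.frame")
  if (keep_fits) attr(out, "fits") <- fits
  out
}

#' Candidate class numbers for stability assessment
#'
#' The best model under each of the three criteria: argmin-BIC, argmin-ICL,
#' argmax-ASW. Ties go to the smaller K (parsimony); duplicates collapse,
#' so the set can have fewer than three members.
#'
#' @param metrics a `model_metrics` table from [scan_models()].
#' @return sorted integer vector of candidate K values.
#' @export
candidate_models <- function(metrics) {
  ok <- metrics[!metrics$failed, , drop = FALSE]
  if (nrow(ok) == 0L) stop("all candidate fits failed")
  argbest <- function(v, maximize = FALSE) {
    v <- if (maximize) -v else v
    ok$K[which(v == min(v, na.rm = TRUE))[1L]]  # ordered by K, so first = smallest K
  }
  ks <- c(argbest(ok$BIC), argbest(ok$ICL))
  if (any(!is.na(ok$ASW))) ks <- c(ks, argbest(ok$ASW, maximize = TRUE))
  sort(unique(as.integer(ks)))
}
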