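# Latent-class model core: maximum-likelihood estimation of a finite mixture
# of independent Bernoulli distributions on a binary indicator matrix, via EM
# with random-responsibility restarts. The measurement model assumes
# conditional independence of the indicators given class and carries no
# covariates: demographics enter only downstream, in the outcome models.

THETA_EPS <- 1e-6  # boundary convention: item probabilities clipped to [eps, 1-eps]

#' Construct and validate latent-class parameters
#'
#' @param pi length-K simplex of class weights.
#' @param theta K x J matrix of item probabilities.
#' @param canonical reorder classes into the canonical order (descending
#'   `pi`, ties broken by lexicographic theta row)?
#' @return object of class `lca_params`.
#' @export
lca_params <- function(pi, theta, canonical = TRUE) {
  theta <- as.matrix(theta)
  if (length(pi) != nrow(theta)) stop("length(pi) must equal nrow(theta)")
  if (abs(sum(pi) - 1) > 1e-8 || any(pi < 0)) stop("`pi` must be a probability simplex")
  theta[] <- pmin(pmax(theta, THETA_EPS), 1 - THETA_EPS)
  p <- structure(list(K = nrow(theta), pi = as.numeric(pi), theta = theta),
                 class = "lca_params")
  if (canonical) p <- canonicalize_params(p) else p
}

#' Canonical class ordering
#'
#' Classes are sorted by descending weight, ties broken by the lexicographic
#' order of the theta rows, so that reports and label assignments are stable
#' under EM label switching. Idempotent.
#'
#' @param params an `lca_params` object.
#' @return the same object with classes reordered.
#' @export
canonicalize_params <- function(params) {
  ord <- do.call(order, c(list(-params$pi),
                          lapply(seq_len(ncol(params$theta)),
                                 function(j) -params$theta[, j])))
  params$pi <- params$pi[ord]
  params$theta <- params$theta[ord, , drop = FALSE]
  rownames(params$theta) <- NULL
  attr(params, "order") <- ord
  params
}

# Per-class log p(x_i | class k): n x K matrix. One matmul per call:
# log-odds form keeps it O(nJK) with a constant per-class offset.
class_logdens <- function(X, params) {
  lt <- log(params$theta)
  lt1 <- log1p(-params$theta)
  X %*% t(lt - lt1) + matrix(rowSums(lt1), nrow(X), params$K, byrow = TRUE)
}

#' Log-likelihood of a latent-class model
#'
#' \eqn{\ell = \sum_i \log \sum_k \pi_k \prod_j \theta_{kj}^{x_{ij}}
#' (1-\theta_{kj})^{1-x_{ij}}}, evaluated with log-sum-exp so 26 indicators
#' cause no underflow.
#'
#' @param X binary matrix (subjects x indicators).
#' @param params `lca_params`.
#' @return scalar log-likelihood.
#' @export
lca_loglik <- function(X, params) {
  X <- check_binary_matrix(X)
  L <- class_logdens(X, params) +
    matrix(log(params$pi), nrow(X), params$K, byrow = TRUE)
  sum(row_logsumexp(L))
}

#' E-step: posterior class responsibilities
#'
#' @inheritParams lca_loglik
#' @return list with `tau` (n x K, rows sum to 1) and `loglik`.
#' @export
lca_e_step <- function(X, params) {
  X <- check_binary_matrix(X)
  L <- class_logdens(X, params) +
    matrix(log(params$pi), nrow(X), params$K, byrow = TRUE)
  lse <- row_logsumexp(L)
  list(tau = exp(L - lse), loglik = sum(lse))
}

#' M-step: parameter update from responsibilities
#'
#' \eqn{\pi_k = \bar\tau_{\cdot k}}, \eqn{\theta_{kj} = \sum_i \tau_{ik}
#' x_{ij} / \sum_i \tau_{ik}}, clipped to the boundary convention. A class
#' with zero total responsibility falls back to the column means (with a
#' warning). If `constrained_items` is non-empty those columns of theta are
#' pooled across classes (used by the discriminative-power refits).
#'
#' @param X binary matrix.
#' @param tau n x K responsibility matrix (rows sum to 1).
#' @param constrained_items integer/character indices of indicators whose
#'   theta is forced equal across classes.
#' @return `lca_params` in the *unsorted* class order of `tau` (callers that
#'   need the canonical order should canonicalize after EM has finished).
#' @export
lca_m_step <- function(X, tau, constrained_items = NULL) {
  X <- check_binary_matrix(X)
  tau <- as.matrix(tau)
  if (any(abs(rowSums(tau) - 1) > 1e-8)) stop("`tau` rows must sum to 1")
  nk <- colSums(tau)
  pi <- nk / nrow(X)
  theta <- t(tau) %*% X
  empty <- nk <= 0
  if (any(empty)) {
    warning(sprintf("empty class(es) %s in M-step; falling back to column means",
                    paste(which(empty), collapse = ", ")))
    theta[empty, ] <- matrix(colMeans(X), sum(empty), ncol(X), byrow = TRUE)
    theta[!empty, ] <- theta[!empty, , drop = FALSE] / nk[!empty]
  } else {
    theta <- theta / nk
  }
  if (!is.null(constrained_items)) {
    pooled <- colMeans(X)  # tau rows sum to 1, so the pooled weighted mean is the column mean
    theta[, constrained_items] <- matrix(pooled[constrained_items],
                                         nrow(theta), length(constrained_items),
                                         byrow = TRUE)
  }
  colnames(theta) <- colnames(X)
  lca_params(pi, theta, canonical = FALSE)
}

# One full EM run from a responsibility initialisation.
run_em <- function(X, tau0, tol, max_iter, constrained_items = NULL) {
  tau <- tau0
  ll_old <- -Inf
  trace <- numeric(0)
  params <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    params <- lca_m_step(X, tau, constrained_items)
    es <- lca_e_step(X, params)
    tau <- es$tau
    trace <- c(trace, es$loglik)
    if (is.finite(ll_old) && abs(es$loglik - ll_old) < tol * (1 + abs(es$loglik))) {
      converged <- TRUE
      ll_old <- es$loglik
      break
    }
    ll_old <- es$loglik
  }
  list(params = params, tau = tau, loglik = ll_old, n_iter = length(trace),
       converged = converged, trace = trace)
}

#' Fit a latent-class model by EM with restarts
#'
#' Runs EM from `n_restarts` random initialisations (responsibility rows
#' drawn from a flat Dirichlet) plus, optionally, one warm start from
#' supplied parameters, and keeps the run with the highest log-likelihood.
#' Convergence when \eqn{|\Delta\ell| < tol \cdot (1+|\ell|)}. `K = 1` is a
#' closed form (column means) and needs no iteration. The result is
#' canonicalized for label switching and is deterministic given `seed`.
#'
#' @param X binary subjects x indicators matrix.
#' @param K number of latent classes (>= 1).
#' @param n_restarts random restarts (default 20).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap per restart.
#' @param seed integer; every random draw in the fit derives from it.
#' @param warm_start optional `lca_params` used as one extra initialisation.
#' @param constrained_items indicators whose theta is pooled across classes
#'   (class-homogeneous specification; see [discriminative_power()]).
#' @return object of class `lca_fit`: `params`, `tau`, `loglik`,
#'   `loglik_trace` (of the winning run), `n_iter`, `converged`,
#'   `n_restarts_used`, `seed`, `n`, `J`.
#' @examples
#' cfg <- cohort_config(seed = 7); cfg$n_subjects <- 400L
#' X <- cohort_matrix(generate_cohort(cfg), comorbid_only = TRUE)
#' fit <- fit_lca(X, K = 2, n_restarts = 5, seed = 7)
#' fit$params$pi
#' @export
fit_lca <- function(X, K, n_restarts = 20, tol = 1e-6, max_iter = 500,
                    seed = NULL, warm_start = NULL, constrained_items = NULL) {
  X <- check_binary_matrix(X)
  n <- nrow(X)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop(sprintf("K = %d exceeds the number of subjects (%d)", K, n))
  if (is.character(constrained_items)) {
    constrained_items <- match(constrained_items, colnames(X))
  }

  if (K == 1L) {
    params <- lca_params(1, matrix(colMeans(X), 1, ncol(X),
                                   dimnames = list(NULL, colnames(X))))
    ll <- lca_loglik(X, params)
    return(structure(list(params = params, tau = matrix(1, n, 1), loglik = ll,
                          loglik_trace = ll, n_iter = 1L, converged = TRUE,
                          n_restarts_used = 0L, seed = seed, n = n, J = ncol(X)),
                     class = "lca_fit"))
  }

  best <- NULL
  with_seed(seed, {
    inits <- list()
    if (!is.null(warm_start)) {
      inits[[length(inits) + 1L]] <- lca_e_step(X, warm_start)$tau
    }
    for (r in seq_len(n_restarts)) {
      g <- matrix(stats::rgamma(n * K, 1), n, K)
      inits[[length(inits) + 1L]] <- g / rowSums(g)
    }
    for (tau0 in inits) {
      run <- run_em(X, tau0, tol, max_iter, constrained_items)
      if (is.null(best) || run$loglik > best$loglik) best <- run
    }
  })

  params <- canonicalize_params(lca_params(best$params$pi, best$params$theta,
                                           canonical = FALSE))
  ord <- attr(params, "order")
  structure(list(params = params,
                 tau = best$tau[, ord, drop = FALSE],
                 loglik = best$loglik,
                 loglik_trace = best$trace,
                 n_iter = best$n_iter,
                 converged = best$converged,
                 n_restarts_used = n_restarts + !is.null(warm_start),
                 seed = seed, n = n, J = ncol(X),
                 constrained_items = constrained_items),
            class = "lca_fit")
}

#' Modal (MAP) class assignment
#'
#' Each subject goes to the class with the largest posterior responsibility;
#' ties break toward the lower canonical class index, so the assignment is
#' exhaustive and exclusive.
#'
#' @param fitted an `lca_fit`.
#' @return named factor with levels `"1"`..`"K"` (names = rownames of the
#'   fitted matrix, if any).
#' @export
map_assign <- function(fitted) {
  k <- max.col(fitted$tau, ties.method = "first")
  part <- factor(as.character(k), levels = as.character(seq_len(fitted$params$K)))
  if (!is.null(rownames(fitted$tau))) names(part) <- rownames(fitted$tau)
  part
}

#' @export
print.lca_fit <- function(x, ...) {
  cat(sprintf("Latent-class fit: K = %d, n = %d, J = %d\n", x$params$K, x$n, x$J))
  cat(sprintf("  log-likelihood %.3f after %d EM iterations (%s)\n",
              x$loglik, x$n_iter, if (x$converged) "converged" else "NOT converged"))
  cat("  class weights:", paste(sprintf("%.3f", x$params$pi), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' @param fitted `lca_fit`.
#' @param path file path; if `NULL` the JSON string is returned.
#' @export
write_lca_json <- function(fitted, path = NULL) {
  obj <- list(K = fitted$params$K, pi = fitted$params$pi,
              theta = fitted$params$theta, loglik = fitted$loglik,
              n_iter = fitted$n_iter, converged = fitted$converged,
              seed = fitted$seed, n = fitted$n, J = fitted$J)
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
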