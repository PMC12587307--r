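# Bootstrap stability of candidate latent-class models: B pairs of random
# subsamples, each pair refitted independently, agreement on the shared
# subjects scored by the clusterwise Jaccard coefficient and the adjusted
# Rand index. The candidate with the highest mean stability wins.

#' Clusterwise Jaccard coefficient between two partitions
#'
#' Each cluster of `partA` (restricted to the subjects shared with `partB`)
#' is matched to the `partB` cluster maximising the Jaccard similarity of
#' the member sets, \eqn{|A \cap B|/|A \cup B|}; the coefficient is the
#' size-weighted mean of the matched similarities and lies in [0, 1].
#' Matching is greedy per cluster by default (each A-cluster independently
#' takes its best match); `method = "assignment"` instead pairs clusters
#' one-to-one in decreasing order of overlap — identical for well-separated
#' clusters.
#'
#' @param partA,partB named factors (names = subject ids).
#' @param shared_ids subjects on which to compare; defaults to the
#'   intersection of the two name sets.
#' @param method `"greedy"` (default) or `"assignment"`.
#' @return scalar in [0, 1].
#' @export
clusterwise_jaccard <- function(partA, partB, shared_ids = NULL,
                                method = c("greedy", "assignment")) {
  method <- match.arg(method)
  if (is.null(names(partA)) || is.null(names(partB))) {
    stop("partitions must be named by subject id")
  }
  if (is.null(shared_ids)) shared_ids <- intersect(names(partA), names(partB))
  if (length(shared_ids) == 0L) stop("no shared subjects between the two partitions")
  a <- droplevels(factor(partA[shared_ids]))
  b <- droplevels(factor(partB[shared_ids]))
  tab <- table(a, b)                      # |A_r intersect B_s|
  sizesA <- rowSums(tab)
  sizesB <- colSums(tab)
  jac <- tab / (outer(sizesA, sizesB, `+`) - tab)
  if (method == "greedy") {
    matched <- apply(jac, 1L, max)
  } else {
    matched <- numeric(nrow(jac))
    jj <- as.matrix(jac)
    for (step in seq_len(min(dim(jj)))) {
      best <- which(jj == max(jj), arr.ind = TRUE)[1L, ]
      matched[best[1L]] <- jj[best[1L], best[2L]]
      jj[best[1L], ] <- -Inf
      jj[, best[2L]] <- -Inf
    }
  }
  sum(sizesA * matched) / sum(sizesA)
}

#' Adjusted Rand index between two partitions
#'
#' Hubert–Arabie chance-corrected pair-counting agreement from the
#' contingency table: \eqn{(\sum_{ij} \binom{n_{ij}}{2} - E) / (M - E)} with
#' \eqn{E} the expectation under random labelling and \eqn{M} the mean of
#' the row- and column-wise pair totals. Equals 1 iff the partitions are
#' identical up to relabelling; invariant to label permutations.
#'
#' @param partA,partB vectors/factors over the same subjects (same length;
#'   if both are named, names must coincide as sets and are used to align).
#' @return scalar ARI (can be negative).
#' @export
adjusted_rand <- function(partA, partB) {
  if (!is.null(names(partA)) && !is.null(names(partB))) {
    if (!setequal(names(partA), names(partB))) {
      stop("partitions are defined on different subject sets")
    }
    partB <- partB[names(partA)]
  } else if (length(partA) != length(partB)) {
    stop("partitions are defined on different subject sets")
  }
  tab <- table(partA, partB)
  n <- sum(tab)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)  # both partitions trivial (single block or all singletons)
  (sum_ij - expected) / (maxi - expected)
}

#' Subsample-pair bootstrap stability of a K-class model
#'
#' Per iteration: two independent subsamples of fraction `f` are drawn
#' without replacement, the K-class model is refitted on each (warm-started
#' from `warm_start` when given, plus fresh random restarts, both fits using
#' the same per-iteration seed so that `f = 1` yields identical fits), the
#' two MAP partitions are restricted to the shared subjects, and the
#' clusterwise Jaccard coefficient and adjusted Rand index are recorded.
#' Iterations whose shared set is empty or whose fit fails are dropped; more
#' than 10\% drops is an error.
#'
#' @param X binary matrix with subject ids as rownames.
#' @param K number of classes.
#' @param B number of subsample pairs (default 100).
#' @param f subsample fraction in (0, 1] (default 0.8, without replacement).
#' @param fit_opts options forwarded to [fit_lca()].
#' @param warm_start optional `lca_params` (e.g., the full-data fit) used as
#'   an extra initialisation in every refit, damping label instability from
#'   local optima.
#' @param seed integer; drives subsample draws and per-iteration fit seeds.
#' @return object of class `stability_result`: per-iteration `jc` and `ari`,
#'   `mean_jc`, `mean_ari`, `K`, `B`, `f`, `n_dropped`, `seed`.
#' @export
assess_stability <- function(X, K, B = 100, f = 0.8, fit_opts = list(),
                             warm_start = NULL, seed = NULL) {
  X <- check_binary_matrix(X)
  n <- nrow(X)
  if (is.null(rownames(X))) rownames(X) <- as.character(seq_len(n))
  m <- max(1L, floor(f * n))
  if (m <= K) stop("subsample size n*f must exceed K")
  if (B < 1) stop("B must be >= 1")

  jc <- ari <- rep(NA_real_, B)
  with_seed(seed, {
    for (iter in seq_len(B)) {
      idx1 <- sort(sample.int(n, m))
      idx2 <- sort(sample.int(n, m))
      it_seed <- if (is.null(seed)) NULL else stage_seed(seed, paste0("stab", iter))
      res <- tryCatch({
        f1 <- do.call(fit_lca, c(list(X = X[idx1, , drop = FALSE], K = K,
                                      seed = it_seed, warm_start = warm_start),
                                 fit_opts))
        f2 <- do.call(fit_lca, c(list(X = X[idx2, , drop = FALSE], K = K,
                                      seed = it_seed, warm_start = warm_start),
                                 fit_opts))
        p1 <- map_assign(f1)
        p2 <- map_assign(f2)
        shared <- intersect(names(p1), names(p2))
        if (length(shared) == 0L) stop("empty shared subject set")
        list(jc = clusterwise_jaccard(p1, p2, shared),
             ari = adjusted_rand(p1[shared], p2[shared]))
      }, error = function(e) NULL)
      if (!is.null(res)) {
        jc[iter] <- res$jc
        ari[iter] <- res$ari
      }
    }
  })
  dropped <- sum(is.na(jc))
  if (dropped > 0.1 * B) {
    stop(sprintf("%d of %d stability iterations failed (> 10%%)", dropped, B))
  }
  structure(list(K = K, jc = jc[!is.na(jc)], ari = ari[!is.na(ari)],
                 mean_jc = mean(jc, na.rm = TRUE), mean_ari = mean(ari, na.rm = TRUE),
                 B = B, f = f, n_dropped = dropped, seed = seed),
            class = "stability_result")
}

#' Final model selection by stability
#'
#' Among the candidate class numbers, picks the one with the highest mean of
#' mean Jaccard coefficient and mean adjusted Rand index; exact ties go to
#' the smaller K.
#'
#' @param candidates integer vector of candidate K values.
#' @param stability list of `stability_result` objects covering every
#'   candidate (names or `K` fields are matched).
#' @return the selected K (integer).
#' @export
select_final_model <- function(candidates, stability) {
  if (length(candidates) == 0L) stop("empty candidate set")
  candidates <- sort(as.integer(candidates))
  ks <- vapply(stability, function(s) s$K, numeric(1))
  score <- vapply(candidates, function(K) {
    i <- match(K, ks)
    if (is.na(i)) stop(sprintf("no stability result for candidate K = %d", K))
    (stability[[i]]$mean_jc + stability[[i]]$mean_ari) / 2
  }, numeric(1))
  candidates[which.max(score)]  # which.max takes the first (smallest K) on ties
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("Stability of K = %d over %d subsample pairs (f = %.2f): mean JC = %.3f, mean ARI = %.3f\n",
              x$K, x$B - x$n_dropped, x$f, x$mean_jc, x$mean_ari))
  invisible(x)
}
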