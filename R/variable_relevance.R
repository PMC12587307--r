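# Variable relevance: how much each comorbidity contributes to the
# clustering, operationalised as an approximate log-Bayes-factor between the
# class-heterogeneous model and a model in which that one indicator is
# forced to have the same probability in every class.

#' Discriminative power of each comorbidity for the clustering
#'
#' For indicator j, the fitted model is refitted with \eqn{\theta_{1j} =
#' \dots = \theta_{Kj}} (all other indicators free, warm-started from the
#' unconstrained fit), and
#' \deqn{DP_j = (BIC_{hom(j)} - BIC_{het}) / 2,}
#' i.e. half the BIC improvement the class-heterogeneous specification buys
#' for that indicator — an approximate log-Bayes-factor. Positive values
#' support the indicator being relevant for the clustering; indicators whose
#' prevalence genuinely does not differ across classes score at or below 0.
#'
#' @param X binary matrix the model was fitted on.
#' @param fitted the selected `lca_fit` with K >= 2.
#' @param fit_opts options for the constrained refits; defaults to warm
#'   start only (`n_restarts = 0`), which bounds the cost to one EM family
#'   per indicator.
#' @param seed integer seed for the refits.
#' @return `data.frame` of class `dp_table`, sorted by descending DP:
#'   `name`, `dp`, `rank`.
#' @export
discriminative_power <- function(X, fitted, fit_opts = list(n_restarts = 0),
                                 seed = NULL) {
  X <- check_binary_matrix(X)
  if (fitted$params$K < 2L) stop("discriminative power requires K >= 2 (no clustering at K = 1)")
  bic_het <- information_criteria(fitted)[["BIC"]]
  nms <- colnames(X)
  if (is.null(nms)) nms <- paste0("item", seq_len(ncol(X)))
  dp <- vapply(seq_len(ncol(X)), function(j) {
    hom <- do.call(fit_lca, c(list(X = X, K = fitted$params$K,
                                   warm_start = fitted$params,
                                   constrained_items = j,
                                   seed = if (is.null(seed)) NULL else stage_seed(seed, paste0("dp", j))),
                              fit_opts))
    (information_criteria(hom)[["BIC"]] - bic_het) / 2
  }, numeric(1))
  out <- data.frame(name = nms, dp = dp)
  out <- out[order(-out$dp), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("dp_table", "data.frame")
  out
}

#' Derive descriptive cluster labels
#'
#' Each cluster is labelled by the names of its top two comorbidities among
#' the indicators that distinguish it (within-cluster frequency strictly
#' above every other cluster's), ranked by discriminative power; names are
#' joined with `+`. A user-supplied `label_map` (character vector of length
#' K, e.g. `c("Cardiovascular", "Psychiatric")`) overrides the automatic
#' labels by canonical cluster index. Labels depend only on cluster
#' contents, not on class indices.
#'
#' @param fitted the selected `lca_fit`.
#' @param dp a `dp_table` from [discriminative_power()].
#' @param X binary matrix the model was fitted on.
#' @param label_map optional character vector of length K.
#' @param top_n number of comorbidities joined per label (default 2).
#' @return character vector of length K, named `"1"`..`"K"`.
#' @export
label_clusters <- function(fitted, dp, X, label_map = NULL, top_n = 2) {
  X <- check_binary_matrix(X)
  K <- fitted$params$K
  if (!is.null(label_map)) {
    if (length(label_map) != K) stop("`label_map` must have one entry per cluster")
    return(stats::setNames(as.character(label_map), as.character(seq_len(K))))
  }
  part <- map_assign(fitted)
  freq <- t(vapply(levels(part), function(k) colMeans(X[part == k, , drop = FALSE]),
                   numeric(ncol(X))))
  dp_rank <- stats::setNames(dp$rank, dp$name)[colnames(X)]
  labels <- vapply(seq_len(K), function(k) {
    others <- freq[-k, , drop = FALSE]
    margin <- freq[k, ] - apply(others, 2L, max)
    distinct <- which(margin > 0)
    if (length(distinct) == 0L) distinct <- order(-margin)[seq_len(top_n)]
    picked <- distinct[order(dp_rank[distinct])][seq_len(min(top_n, length(distinct)))]
    paste(colnames(X)[picked], collapse = "+")
  }, character(1))
  stats::setNames(labels, as.character(seq_len(K)))
}
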