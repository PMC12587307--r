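# Outcome analysis: the no-comorbidity stratum rejoins the clustered
# subjects as the reference group, and healthcare-resource outcomes are
# compared across groups with Cohen's d and univariable plus
# covariate-adjusted (age, sex, SES) linear models.

OUTCOME_VARS <- c("nurse_visits", "pcp_visits", "sick_leave_days", "dispensations")

#' Full-cohort partition from a fitted model
#'
#' Subjects with at least one comorbidity receive their MAP class; subjects
#' with an all-zero indicator row form the `"none"` stratum, a cluster in
#' itself that serves as the reference group downstream.
#'
#' @param cohort a `cohort_table`.
#' @param fitted an `lca_fit` estimated on the comorbid rows of `cohort`
#'   (matched by subject id).
#' @return named factor over all subjects with levels `"none", "1", ..., "K"`.
#' @export
cohort_partition <- function(cohort, fitted) {
  part_com <- map_assign(fitted)
  X <- cohort_matrix(cohort)
  lv <- c("none", levels(part_com))
  out <- factor(rep("none", nrow(cohort)), levels = lv)
  names(out) <- cohort$subject_id
  comorbid_ids <- rownames(X)[rowSums(X) > 0]
  if (!all(comorbid_ids %in% names(part_com))) {
    stop("fitted model does not cover all comorbid subjects of the cohort")
  }
  out[comorbid_ids] <- as.character(part_com[comorbid_ids])
  out
}

#' Within-group comorbidity frequency matrix
#'
#' One row per cluster, one for the no-comorbidity stratum (all zeros by
#' construction) and a final whole-sample row; values in [0, 1]. This is
#' the heat-map layout used to characterise and label clusters. Empty
#' clusters yield a row of `NaN`.
#'
#' @param X full binary matrix (all subjects).
#' @param partition factor over the rows of `X` with a `"none"` level.
#' @return numeric matrix, (K + 2) x J.
#' @export
cluster_profile <- function(X, partition) {
  X <- check_binary_matrix(X)
  partition <- as.factor(partition)
  if (length(partition) != nrow(X)) stop("partition length must match rows of X")
  groups <- levels(partition)
  groups <- c(setdiff(groups, "none"), intersect("none", groups))
  rows <- t(vapply(groups, function(g) colMeans(X[partition == g, , drop = FALSE]),
                   numeric(ncol(X))))
  rbind(rows, all = colMeans(X))
}

#' Cohen's d from summary statistics
#'
#' \eqn{d = (m_1 - m_2)/s_p} with the pooled standard deviation
#' \eqn{s_p = \sqrt{((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}}.
#' Conventional anchors: 0.2 small, 0.5 medium, 0.8 large.
#'
#' @param m1,s1,n1 mean, SD, size of group 1.
#' @param m2,s2,n2 mean, SD, size of group 2.
#' @return scalar d.
#' @export
cohens_d <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (s1 < 0 || s2 < 0) stop("SDs must be non-negative")
  if (s1 == 0 && s2 == 0) stop("Cohen's d undefined when both SDs are zero")
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  (m1 - m2) / sp
}

# Cohen's d from raw vectors.
cohens_d_vec <- function(x, y) {
  cohens_d(mean(x), stats::sd(x), length(x), mean(y), stats::sd(y), length(y))
}

# Assemble the model frame for the effect models; sick-leave outcomes are
# restricted to subjects eligible for sick leave (not on disability
# pension). Complete-case on the covariates actually in the model.
effects_frame <- function(cohort, partition, outcome, adjusted) {
  df <- data.frame(
    y = cohort[[outcome]],
    cluster = stats::relevel(factor(partition, exclude = NULL), ref = "none"),
    age = cohort$age,
    sex = cohort$sex,
    ses = cohort$ses
  )
  if (outcome == "sick_leave_days") df <- df[cohort$sick_leave_eligible == 1, ]
  vars <- c("y", "cluster", if (adjusted) c("age", "sex", "ses"))
  df[stats::complete.cases(df[, vars]), , drop = FALSE]
}

#' Linear models for cluster effects on an outcome
#'
#' Ordinary least squares of the outcome on the cluster indicator(s), with
#' the no-comorbidity stratum as reference; the adjusted model adds age
#' (per-year), sex (male reference) and SES quintile dummies (Q1, the least
#' deprived, as reference). Complete-case on the included covariates;
#' sick-leave models use only sick-leave-eligible subjects. 95\% CIs come
#' from the t distribution.
#'
#' @param cohort a `cohort_table`.
#' @param partition full-cohort partition from [cohort_partition()].
#' @param outcome one of `nurse_visits`, `pcp_visits`, `sick_leave_days`,
#'   `dispensations`.
#' @param adjusted add the sociodemographic covariates?
#' @return `data.frame`: one row per non-intercept term with `term`,
#'   `estimate`, `ci_lo`, `ci_hi`, `p`, plus `outcome`, `model`, `n`.
#' @export
fit_linear_effects <- function(cohort, partition, outcome, adjusted = FALSE) {
  if (!outcome %in% names(cohort)) stop(sprintf("outcome `%s` not found in cohort", outcome))
  df <- effects_frame(cohort, partition, outcome, adjusted)
  form <- if (adjusted) y ~ cluster + age + sex + ses else y ~ cluster
  fit <- stats::lm(form, data = df)
  if (any(is.na(stats::coef(fit)))) {
    stop(sprintf("rank-deficient design; collinear terms: %s",
                 paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", ")))
  }
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = 0.95)
  keep <- setdiff(rownames(sm), "(Intercept)")
  data.frame(term = keep,
             estimate = sm[keep, "Estimate"],
             ci_lo = ci[keep, 1L],
             ci_hi = ci[keep, 2L],
             p = sm[keep, "Pr(>|t|)"],
             outcome = outcome,
             model = if (adjusted) "adjusted" else "univariable",
             n = nrow(df),
             row.names = NULL)
}

#' Group comparison test dispatch
#'
#' Quantitative variables: Student's t-test for two groups (Kruskal-Wallis
#' instead when `skewed = TRUE` or with more than two groups); categorical
#' variables: Pearson's chi-squared test on the contingency table (with a
#' warning when an expected cell count is zero).
#'
#' @param cohort a `cohort_table`.
#' @param partition grouping factor over subjects.
#' @param variable column name to compare.
#' @param skewed treat a quantitative variable as skewed?
#' @return list: `method`, `statistic`, `df` (if defined), `p.value`.
#' @export
compare_groups <- function(cohort, partition, variable, skewed = FALSE) {
  x <- cohort[[variable]]
  if (is.null(x)) stop(sprintf("variable `%s` not found", variable))
  g <- droplevels(as.factor(partition))
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- droplevels(g[ok])
  if (is.numeric(x) && !skewed && nlevels(g) == 2L) {
    ht <- stats::t.test(x ~ g, var.equal = TRUE)
  } else if (is.numeric(x)) {
    ht <- stats::kruskal.test(x, g)
  } else {
    tab <- table(x, g)
    exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(exp_counts == 0)) warning("expected cell count of zero in chi-squared table")
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  }
  list(method = ht$method,
       statistic = unname(ht$statistic),
       df = if (!is.null(ht$parameter)) unname(ht$parameter) else NA_real_,
       p.value = ht$p.value)
}

#' Full outcome effect table
#'
#' The complete grid over the four outcomes x clusters x {univariable,
#' adjusted}: group mean, SD and n, Cohen's d against the no-comorbidity
#' reference, and the cluster regression coefficient with 95\% CI and
#' p-value. Covariate coefficient rows of the adjusted models are attached
#' as the `covariates` attribute. A failed model marks its cells `NA`
#' rather than aborting the report.
#'
#' @param cohort a `cohort_table`.
#' @param partition full-cohort partition including the `"none"` stratum.
#' @param outcomes outcome columns (default: the four resource-use
#'   measures).
#' @return `data.frame` of class `effect_table`, one row per outcome x
#'   cluster x model.
#' @export
outcome_report <- function(cohort, partition, outcomes = OUTCOME_VARS) {
  partition <- as.factor(partition)
  if (!"none" %in% levels(partition)) stop("partition must include the `none` reference stratum")
  clusters <- setdiff(levels(partition), "none")
  rows <- list()
  covars <- list()
  for (outc in outcomes) {
    keep <- if (outc == "sick_leave_days") cohort$sick_leave_eligible == 1 else rep(TRUE, nrow(cohort))
    y <- cohort[[outc]][keep]
    g <- partition[keep]
    ref <- y[g == "none"]
    stats_by <- lapply(c("none", clusters), function(k) {
      v <- y[g == k]
      list(mean = mean(v), sd = stats::sd(v), n = length(v))
    })
    names(stats_by) <- c("none", clusters)
    for (model in c("univariable", "adjusted")) {
      eff <- tryCatch(fit_linear_effects(cohort, partition, outc, adjusted = model == "adjusted"),
                      error = function(e) NULL)
      if (model == "adjusted" && !is.null(eff)) {
        covars[[outc]] <- eff[!startsWith(eff$term, "cluster"), ]
      }
      for (k in clusters) {
        term <- paste0("cluster", k)
        row <- if (!is.null(eff) && term %in% eff$term) eff[eff$term == term, ] else NULL
        d_k <- tryCatch(cohens_d(stats_by[[k]]$mean, stats_by[[k]]$sd, stats_by[[k]]$n,
                                 stats_by$none$mean, stats_by$none$sd, stats_by$none$n),
                        error = function(e) NA_real_)
        rows[[length(rows) + 1L]] <- data.frame(
          outcome = outc, cluster = k, model = model,
          mean = stats_by[[k]]$mean, sd = stats_by[[k]]$sd, n_group = stats_by[[k]]$n,
          ref_mean = stats_by$none$mean, ref_sd = stats_by$none$sd, ref_n = stats_by$none$n,
          cohens_d = d_k,
          beta = if (is.null(row)) NA_real_ else row$estimate,
          ci_lo = if (is.null(row)) NA_real_ else row$ci_lo,
          ci_hi = if (is.null(row)) NA_real_ else row$ci_hi,
          p = if (is.null(row)) NA_real_ else row$p,
          n_model = if (is.null(row)) NA_integer_ else row$n)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "covariates") <- do.call(rbind, covars)
  class(out) <- c("effect_table", "data.frame")
  out
}
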