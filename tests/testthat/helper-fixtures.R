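# Fixtures are generated in code: no data files.

# A scaled-down default cohort (same latent structure, fewer subjects).
small_cohort <- function(n = 600L, seed = 1L) {
  cfg <- cohort_config(seed = seed)
  cfg$n_subjects <- as.integer(n)
  generate_cohort(cfg)
}

# Binary matrix from two well-separated class profiles (separation >= 0.6).
separated_X <- function(n = 2000L, J = 6L, seed = 1L,
                        p_hi = 0.8, p_lo = 0.15, pi1 = 0.5) {
  stopifnot(J %% 2 == 0)
  th1 <- c(rep(p_hi, J / 2), rep(p_lo, J / 2))
  th2 <- c(rep(p_lo, J / 2), rep(p_hi, J / 2))
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    z <- stats::rbinom(n, 1, 1 - pi1) + 1L
    theta <- rbind(th1, th2)
    X <- matrix(stats::rbinom(n * J, 1, theta[z, ]), n, J)
    rownames(X) <- sprintf("r%04d", seq_len(n))
    list(X = X, z = z, theta = theta)
  })
}

# Minimal cohort-shaped data frame for the outcome models: two groups with
# exactly specified means (values alternate m - 0.5 / m + 0.5).
two_group_cohort <- function(m_ref, n_ref, m_grp, n_grp, outcome = "nurse_visits") {
  stopifnot(n_ref %% 2 == 0, n_grp %% 2 == 0)
  y <- c(rep(c(m_ref - 0.5, m_ref + 0.5), n_ref / 2),
         rep(c(m_grp - 0.5, m_grp + 0.5), n_grp / 2))
  n <- n_ref + n_grp
  df <- data.frame(subject_id = sprintf("S%05d", seq_len(n)),
                   age = rep(50, n),
                   sex = factor(rep("female", n), levels = c("male", "female")),
                   ses = factor(rep("Q1", n), levels = paste0("Q", 1:5)),
                   ever_smoker = rep(0L, n),
                   disease_duration = rep(10, n),
                   nurse_visits = 0, pcp_visits = 0, sick_leave_days = 0,
                   sick_leave_eligible = 1L, dispensations = 0)
  df[[outcome]] <- y
  class(df) <- c("cohort_table", "data.frame")
  part <- factor(rep(c("none", "1"), c(n_ref, n_grp)), levels = c("none", "1"))
  names(part) <- df$subject_id
  list(cohort = df, partition = part)
}

# Ground-truth full-cohort partition of a synthetic cohort (the generator's
# class labels, with the no-comorbidity stratum as "none").
truth_partition_full <- function(cohort) {
  p <- factor(as.character(cohort$true_class),
              levels = levels(cohort$true_class))
  names(p) <- cohort$subject_id
  p
}

# Independent naive silhouette: O(n^2) double loop, no shared code with the
# package implementation.
naive_asw <- function(X, part) {
  n <- nrow(X)
  d <- function(x, y) { u <- sum(x | y); if (u == 0) NaN else 1 - sum(x & y) / u }
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) D[i, j] <- d(X[i, ], X[j, ])
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(part == part[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(levels(factor(part)), as.character(part[i])),
                    function(g) mean(D[i, part == g]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# Independent ARI oracle: direct pair counting over all C(n,2) subject pairs.
pair_count_ari <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa && !sb) n10 <- n10 + 1
    else if (!sa && sb) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / den
}
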