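test_that("log-likelihood matches closed forms and a brute-force mixture sum", {
  # K = 1, J = 1, theta = 0.5: each row contributes log 0.5
  p1 <- lca_params(1, matrix(0.5, 1, 1))
  expect_equal(lca_loglik(matrix(c(1, 0), 2, 1), p1), 2 * log(0.5), tolerance = 1e-12)

  # boundary convention: theta clipped at 1 - 1e-6
  pb <- lca_params(1, matrix(1, 1, 3))
  Xb <- matrix(1, 4, 3)
  expect_equal(lca_loglik(Xb, pb), 12 * log(1 - 1e-6), tolerance = 1e-9)

  # n = 4, J = 2, K = 2: enumerate both mixture terms directly
  X <- rbind(c(1, 0), c(0, 0), c(1, 1), c(0, 1))
  pi <- c(0.3, 0.7)
  th <- rbind(c(0.8, 0.2), c(0.4, 0.9))
  pm <- lca_params(pi, th, canonical = FALSE)
  brute <- sum(apply(X, 1, function(x) {
    log(sum(vapply(1:2, function(k) {
      pi[k] * prod(th[k, ]^x * (1 - th[k, ])^(1 - x))
    }, numeric(1))))
  }))
  expect_equal(lca_loglik(X, pm), brute, tolerance = 1e-10)

  expect_error(lca_loglik(matrix(c(0, 2), 1, 2), pm), "non-binary")
})

test_that("E-step responsibilities follow Bayes' rule", {
  X <- rbind(c(1, 1), c(0, 0))
  # identical rows of theta: posteriors equal the prior
  sym <- lca_params(c(0.5, 0.5), rbind(c(0.3, 0.6), c(0.3, 0.6)), canonical = FALSE)
  expect_equal(lca_e_step(X, sym)$tau, matrix(0.5, 2, 2), tolerance = 1e-12,
               ignore_attr = TRUE)

  # dominating likelihood pulls the posterior to ~1
  dom <- lca_params(c(0.5, 0.5), rbind(c(0.999, 0.999), c(0.001, 0.001)),
                    canonical = FALSE)
  expect_gt(lca_e_step(matrix(1, 1, 2), dom)$tau[1, 1], 0.999)

  # single row, hand-computed posterior
  pi <- c(0.4, 0.6)
  th <- rbind(c(0.7, 0.2), c(0.1, 0.9))
  x <- c(1, 0)
  lik <- c(pi[1] * 0.7 * 0.8, pi[2] * 0.1 * 0.1)
  es <- lca_e_step(matrix(x, 1), lca_params(pi, th, canonical = FALSE))
  expect_equal(as.numeric(es$tau), lik / sum(lik), tolerance = 1e-12)
  expect_equal(es$loglik, log(sum(lik)), tolerance = 1e-12)
  expect_equal(rowSums(lca_e_step(X, sym)$tau), c(1, 1), tolerance = 1e-12)
})

test_that("M-step computes responsibility-weighted parameters", {
  X <- rbind(c(1, 0), c(1, 1), c(0, 0))
  # all mass on class 1
  tau <- cbind(rep(1, 3), rep(0, 3))
  expect_warning(p <- lca_m_step(X, tau), "empty class")
  expect_equal(p$pi, c(1, 0))
  expect_equal(as.numeric(p$theta[1, ]), colMeans(X), tolerance = 1e-12)

  # uniform tau: both rows equal the column means
  pu <- lca_m_step(X, matrix(0.5, 3, 2))
  expect_equal(pu$theta[1, ], pu$theta[2, ], tolerance = 1e-12)
  expect_equal(as.numeric(pu$theta[1, ]), colMeans(X), tolerance = 1e-12)

  # hand-set tau, weighted means by hand
  tau <- rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.5, 0.5))
  ph <- lca_m_step(X, tau)
  expect_equal(ph$pi, colSums(tau) / 3, tolerance = 1e-12)
  expect_equal(as.numeric(ph$theta[, 1]),
               c(sum(tau[, 1] * X[, 1]) / sum(tau[, 1]),
                 sum(tau[, 2] * X[, 1]) / sum(tau[, 2])), tolerance = 1e-12)
  expect_error(lca_m_step(X, tau * 2), "sum to 1")
})

test_that("K = 1 fit is the closed-form Bernoulli model", {
  X <- separated_X(n = 200, seed = 8)$X
  fit <- fit_lca(X, K = 1)
  expect_equal(as.numeric(fit$params$theta), colMeans(X), tolerance = 1e-12)
  expect_identical(fit$n_iter, 1L)
  cm <- colMeans(X)
  ll <- sum(colSums(X) * log(cm) + (nrow(X) - colSums(X)) * log(1 - cm))
  expect_equal(fit$loglik, ll, tolerance = 1e-8)
})

test_that("EM is monotone, deterministic under a seed, and recovers separated profiles", {
  sim <- separated_X(n = 2000, J = 6, seed = 21, pi1 = 0.65)
  fit <- fit_lca(sim$X, K = 2, n_restarts = 5, seed = 31)
  expect_true(all(diff(fit$loglik_trace) >= -1e-10))
  expect_true(fit$converged)
  expect_equal(fit$loglik, lca_loglik(sim$X, fit$params), tolerance = 1e-8)
  expect_equal(rowSums(fit$tau), rep(1, nrow(sim$X)), tolerance = 1e-10,
               ignore_attr = TRUE)

  # recovery within 0.05 element-wise (classes in canonical order)
  truth <- sim$theta[order(-c(mean(sim$z == 1), mean(sim$z == 2))), ]
  expect_lt(max(abs(fit$params$theta - truth)), 0.05)

  fit2 <- fit_lca(sim$X, K = 2, n_restarts = 5, seed = 31)
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$loglik, fit2$loglik)

  expect_error(fit_lca(sim$X[1:3, ], K = 5), "exceeds")
})

test_that("canonical ordering sorts by weight and is idempotent", {
  p <- lca_params(c(0.2, 0.8), rbind(c(0.9, 0.1), c(0.2, 0.3)), canonical = FALSE)
  cp <- canonicalize_params(p)
  expect_equal(cp$pi, c(0.8, 0.2))
  expect_equal(cp$theta[1, ], c(0.2, 0.3), ignore_attr = TRUE)
  cpp <- canonicalize_params(cp)
  expect_equal(cpp$pi, cp$pi)
  expect_equal(cpp$theta, cp$theta)
  # weight ties break on the lexicographic theta row
  pt <- canonicalize_params(lca_params(c(0.5, 0.5), rbind(c(0.1, 0.9), c(0.7, 0.2)),
                                       canonical = FALSE))
  expect_equal(pt$theta[1, 1], 0.7)
})

test_that("MAP assignment is exhaustive, exclusive, and breaks ties low", {
  sim <- separated_X(n = 150, J = 4, seed = 2)
  fit <- fit_lca(sim$X, K = 2, n_restarts = 3, seed = 5)
  part <- map_assign(fit)
  expect_identical(length(part), nrow(sim$X))
  expect_false(anyNA(part))
  expect_identical(names(part), rownames(sim$X))

  fake <- fit
  fake$tau <- rbind(c(0.9, 0.1), c(0.5, 0.5), c(0.1, 0.9))
  expect_identical(as.character(map_assign(fake)), c("1", "1", "2"))
})

test_that("fitted models serialize to JSON and back", {
  sim <- separated_X(n = 100, J = 4, seed = 3)
  fit <- fit_lca(sim$X, K = 2, n_restarts = 2, seed = 4)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_lca_json(fit, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$K, 2)
  expect_equal(obj$pi, fit$params$pi, tolerance = 1e-12)
  expect_equal(obj$loglik, fit$loglik, tolerance = 1e-12)
})
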