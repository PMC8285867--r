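test_that("single-component fit equals the closed-form Gaussian MLE", {
  withr::with_seed(41, X <- matrix(rnorm(100 * 2), 100, 2))
  n <- nrow(X); d <- ncol(X)
  fit <- fit_gmm(X, 1, "VVV")
  expect_equal(unname(fit$mean[1, ]), unname(colMeans(X)), tolerance = 1e-8)
  Sig <- crossprod(sweep(X, 2, colMeans(X))) / n
  # closed form: -(n/2) (d log 2pi + log|Sigma_hat| + d)
  ll_closed <- -(n / 2) * (d * log(2 * pi) + determinant(Sig)$modulus[1] + d)
  expect_equal(fit$loglik, ll_closed, tolerance = 1e-6)
  expect_equal(bic_score(fit, n), 2 * ll_closed - 5 * log(n),
               tolerance = 1e-6)
})

test_that("parameter counts follow the covariance constraint", {
  # K = 1, VVV, d = 2: 0 + 2 + 3; K = 2, EII, d = 3: 1 + 6 + 1
  withr::with_seed(5, {
    X2 <- matrix(rnorm(60 * 2), 60, 2)
    X3 <- matrix(rnorm(60 * 3), 60, 3)
  })
  expect_equal(fit_gmm(X2, 1, "VVV")$n_params, 5)
  expect_equal(fit_gmm(X3, 2, "EII")$n_params, 8)
  expect_equal(fit_gmm(X3, 2, "VVV")$n_params, 1 + 6 + 12)
  expect_equal(fit_gmm(X3, 3, "EEI")$n_params, 2 + 9 + 3)
  # n_params strictly increases with K for a fixed model
  for (m in c("EII", "VII", "EEI", "VVI", "EEE", "VVV")) {
    np <- vapply(1:4, function(K) fit_gmm(X3, K, m)$n_params, 0)
    expect_true(all(diff(np) > 0))
  }
})

test_that("EM log-likelihood is non-decreasing over iterations", {
  gen <- generate_districts(synthetic_config(n_units = 120,
                                             n_indicators = 4, K_true = 3,
                                             separation = 3, seed = 8))
  for (m in c("EII", "VVI", "VVV")) {
    fit <- fit_gmm(standardize(gen$table), 3, m)
    expect_true(all(diff(fit$loglik_trace) > -1e-8))
    expect_true(fit$converged)
    expect_equal(unname(rowSums(fit$responsibilities)), rep(1, 120),
                 tolerance = 1e-12)
    expect_equal(sum(fit$pi), 1, tolerance = 1e-12)
  }
})

test_that("well-separated three-component data are recovered (ARI >= 0.95)", {
  for (s in 1:10) {
    gen <- generate_districts(synthetic_config(n_units = 180,
                                               n_indicators = 6, K_true = 3,
                                               separation = 6, seed = s))
    fit <- fit_gmm(standardize(gen$table), 3, "VVV", seed = s)
    expect_gte(adjusted_rand_index(fit$labels, gen$labels), 0.95)
  }
})

test_that("loglik agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust") # Mclust() needs its namespace attached
  gen <- generate_districts(synthetic_config(n_units = 150,
                                             n_indicators = 4, K_true = 2,
                                             separation = 4, seed = 12))
  X <- standardize(gen$table)$values
  for (m in c("EII", "EEI", "EEE", "VVV")) {
    fit <- fit_gmm(X, 2, m)
    # evaluate OUR loglik function at mclust's fitted parameters
    mc <- mclust::Mclust(X, G = 2, modelNames = m, verbose = FALSE)
    sig <- lapply(1:2, function(k) {
      s <- mc$parameters$variance$sigma
      if (!is.null(s)) s[, , k] else diag(mc$parameters$variance$sigmasq[1],
                                          ncol(X))
    })
    ll <- strataminer:::gmm_loglik(X, mc$parameters$pro,
                                   t(mc$parameters$mean), sig)
    expect_equal(ll, mc$loglik, tolerance = 1e-4)
    # and the two optimizers land on the same optimum
    expect_equal(fit$loglik, mc$loglik, tolerance = 1e-3)
  }
})

test_that("BIC is invariant to component relabeling", {
  gen <- generate_districts(synthetic_config(n_units = 90, n_indicators = 3,
                                             K_true = 2, separation = 5,
                                             seed = 14))
  X <- standardize(gen$table)$values
  f <- fit_gmm(X, 2, "VVI")
  perm <- list(pi = f$pi[2:1], mu = f$mean[2:1, ], sigma = f$cov[2:1])
  ll_perm <- strataminer:::gmm_loglik(X, perm$pi, perm$mu, perm$sigma)
  expect_equal(ll_perm, f$loglik, tolerance = 1e-9)
})

test_that("BIC selection recovers K on structured data and K = 1 on null", {
  gen <- generate_districts(synthetic_config(n_units = 200,
                                             n_indicators = 6, K_true = 3,
                                             separation = 5, seed = 19))
  sel <- select_gmm(standardize(gen$table), K_range = 1:6, seed = 19)
  expect_equal(sel$K, 3)
  expect_gte(adjusted_rand_index(sel$labels, gen$labels), 0.9)
  expect_true(all(c("K", "cov_model", "BIC", "converged") %in%
                  names(sel$bic_table)))
  best <- max(sel$bic_table$BIC[sel$bic_table$converged])
  expect_equal(bic_score(sel$fit, 200), best, tolerance = 1e-9)

  nul <- generate_null(synthetic_config(n_units = 200, n_indicators = 5,
                                        K_true = 0, seed = 23),
                       mode = "gaussian")
  sel0 <- select_gmm(standardize(nul), K_range = 1:4, seed = 23)
  expect_equal(sel0$K, 1)
})

test_that("overfit K on large-n null scores lower BIC than K = 1", {
  nul <- generate_null(synthetic_config(n_units = 1000, n_indicators = 3,
                                        K_true = 0, seed = 29),
                       mode = "gaussian")
  X <- standardize(nul)$values
  b1 <- bic_score(fit_gmm(X, 1, "VVV"), 1000)
  b5 <- bic_score(fit_gmm(X, 5, "VVV", seed = 29), 1000)
  expect_gt(b1, b5)
})

test_that("ARI agrees with the reference implementation", {
  skip_if_not_installed("mclust")
  withr::with_seed(31, {
    a <- sample.int(4, 60, replace = TRUE)
    b <- sample.int(3, 60, replace = TRUE)
  })
  expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
               tolerance = 1e-12)
  expect_equal(adjusted_rand_index(a, a), 1)
})
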