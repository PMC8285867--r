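#' Gaussian mixture model-based clustering with BIC selection
#'
#' Fits finite Gaussian mixtures by expectation-maximization under six
#' covariance parameterizations named in the usual volume/shape/orientation
#' scheme:
#'
#' * `EII` — spherical, equal volume: \eqn{\Sigma_k = \sigma^2 I}
#' * `VII` — spherical, varying volume: \eqn{\Sigma_k = \sigma_k^2 I}
#' * `EEI` — diagonal, equal: \eqn{\Sigma_k = \Lambda}
#' * `VVI` — diagonal, varying: \eqn{\Sigma_k = \Lambda_k}
#' * `EEE` — full covariance, shared: \eqn{\Sigma_k = \Sigma}
#' * `VVV` — full covariance, per component: \eqn{\Sigma_k}
#'
#' Initialization is a deterministic Ward-linkage agglomerative partition
#' cut at `K` converted to one-hot responsibilities, so a fit is a pure
#' function of the data, `K`, the model and the seed (the seed only matters
#' for random restarts after a component collapse).
#'
#' @name gmm
NULL

GMM_MODELS <- c("EII", "VII", "EEI", "VVI", "EEE", "VVV")

gmm_cov_params <- function(model, K, d) {
  switch(model,
         EII = 1, VII = K, EEI = d, VVI = K * d,
         EEE = d * (d + 1) / 2, VVV = K * d * (d + 1) / 2,
         stop("unknown covariance model: ", model, call. = FALSE))
}

gmm_n_params <- function(model, K, d) {
  (K - 1) + K * d + gmm_cov_params(model, K, d)
}

#' Fit a Gaussian mixture by EM under a covariance constraint
#'
#' @param table an [indicator_table()] (expected standardized) or numeric
#'   matrix.
#' @param K number of mixture components, `1 <= K < n`.
#' @param cov_model one of `"EII"`, `"VII"`, `"EEI"`, `"VVI"`, `"EEE"`,
#'   `"VVV"`.
#' @param init either `"ward"` (deterministic hierarchical initialization,
#'   default), `"random"`, or an integer vector of initial hard labels.
#' @param seed seed for random restarts (and `init = "random"`).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param max_restarts random restarts attempted after a component collapse
#'   (mixing weight below `1/(10n)`) before the fit is flagged.
#' @return A `gmm_fit` list: `K`, `cov_model`, `pi`, `mean` (K x d),
#'   `cov` (list of K d x d matrices), `loglik`, `loglik_trace`, `n_params`,
#'   `responsibilities` (n x K), `labels`, `converged`, `collapsed`,
#'   `n_iter`.
#' @export
fit_gmm <- function(table, K, cov_model = "VVV", init = "ward", seed = 1L,
                    tol = 1e-6, max_iter = 500L, max_restarts = 5L) {
  X <- as_values_matrix(table)
  n <- nrow(X); d <- ncol(X)
  cov_model <- match.arg(cov_model, GMM_MODELS)
  if (K < 1 || K >= n) stop("need 1 <= K < n_units", call. = FALSE)
  z0 <- gmm_init_labels(X, K, init, seed)
  fit <- try_em(X, K, cov_model, z0, tol, max_iter)
  r <- 0L
  while (fit$collapsed && r < max_restarts) {
    r <- r + 1L
    z0 <- withr::with_seed(as.integer(seed) + r, sample.int(K, n,
                                                            replace = TRUE))
    # ensure all K labels occur
    z0[seq_len(K)] <- seq_len(K)
    fit2 <- try_em(X, K, cov_model, z0, tol, max_iter)
    if (!fit2$collapsed) { fit <- fit2; break }
    if (fit2$loglik > fit$loglik) fit <- fit2
  }
  fit
}

gmm_init_labels <- function(X, K, init, seed) {
  n <- nrow(X)
  if (is.numeric(init) && length(init) == n) return(as.integer(init))
  if (identical(init, "random")) {
    z <- withr::with_seed(as.integer(seed), sample.int(K, n, replace = TRUE))
    z[seq_len(K)] <- seq_len(K)
    return(z)
  }
  if (K == 1L) return(rep(1L, n))
  hc <- stats::hclust(stats::dist(X), method = "ward.D2")
  stats::cutree(hc, k = K)
}

try_em <- function(X, K, cov_model, z0, tol, max_iter) {
  n <- nrow(X); d <- ncol(X)
  floor_eig <- 1e-6 * mean(apply(X, 2, stats::var))
  if (!is.finite(floor_eig) || floor_eig <= 0) floor_eig <- 1e-10
  resp <- matrix(0, n, K)
  resp[cbind(seq_len(n), z0)] <- 1
  code <- match(cov_model, GMM_MODELS) - 1L
  out <- .em_fit_cpp(X, resp, code, tol, as.integer(max_iter), floor_eig)
  sigma <- lapply(seq_len(K), function(k) out$sigma[, , k, drop = TRUE])
  if (d == 1) sigma <- lapply(sigma, function(s) matrix(s, 1, 1))
  mu <- matrix(out$mu, K, d, dimnames = list(NULL, colnames(X)))
  labels <- max.col(out$resp, ties.method = "first")
  structure(list(K = K, cov_model = cov_model, pi = as.vector(out$pi),
                 mean = mu, cov = sigma, loglik = out$loglik,
                 loglik_trace = as.vector(out$loglik_trace),
                 n_params = gmm_n_params(cov_model, K, d),
                 responsibilities = out$resp, labels = labels,
                 converged = out$converged, collapsed = out$collapsed,
                 n_iter = out$n_iter),
            class = "gmm_fit")
}

spd_floor <- function(S, floor_eig) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < floor_eig) {
    S <- e$vectors %*% diag(pmax(e$values, floor_eig),
                            nrow(S)) %*% t(e$vectors)
  }
  S
}

gmm_estep <- function(X, par) {
  n <- nrow(X); d <- ncol(X); K <- length(par$pi)
  logdens <- matrix(0, n, K)
  Id <- diag(d)
  for (k in seq_len(K)) {
    R <- tryCatch(chol(par$sigma[[k]]),
                  error = function(e) chol(spd_floor(par$sigma[[k]],
                                                     1e-8)))
    logdet <- 2 * sum(log(diag(R)))
    Xc <- X - rep(par$mu[k, ], each = n)
    Z <- Xc %*% backsolve(R, Id)
    quad <- rowSums(Z^2)
    logdens[, k] <- -0.5 * (d * log(2 * pi) + logdet + quad) +
      log(par$pi[k])
  }
  mx <- do.call(pmax, as.data.frame(logdens))
  lse <- mx + log(rowSums(exp(logdens - mx)))
  list(resp = exp(logdens - lse), loglik = sum(lse))
}

#' Log-likelihood of data under a fitted (or constructed) Gaussian mixture
#'
#' @param X numeric matrix of observations.
#' @param pi mixing weights.
#' @param mu K x d matrix of means.
#' @param sigma list of K covariance matrices.
#' @return total log-likelihood.
#' @keywords internal
gmm_loglik <- function(X, pi, mu, sigma) {
  gmm_estep(as.matrix(X), list(pi = pi, mu = as.matrix(mu),
                               sigma = sigma))$loglik
}

#' BIC of a fitted Gaussian mixture
#'
#' Uses the larger-is-better sign convention
#' \eqn{BIC = 2\,\log L - p \log n}, where `p` counts free parameters:
#' `(K - 1)` mixing weights, `K d` means, and the covariance parameters of
#' the constraint (`EII`: 1, `VII`: K, `EEI`: d, `VVI`: Kd,
#' `EEE`: d(d+1)/2, `VVV`: Kd(d+1)/2). The model with the largest BIC is
#' preferred.
#'
#' @param fit a `gmm_fit` from [fit_gmm()].
#' @param n number of observations the fit used.
#' @return scalar BIC.
#' @export
bic_score <- function(fit, n) {
  2 * fit$loglik - fit$n_params * log(n)
}

#' Model-based clustering: search over K and covariance models by BIC
#'
#' Fits every combination of `K_range` and `models`, scores each converged
#' fit by [bic_score()], and returns the hard partition of the
#' BIC-maximizing fit together with the full selection table. BIC ties
#' (within `1e-9`) break to the smaller `K`, then to the earlier model in
#' `models` order (parsimony). The Ward initialization tree is computed
#' once and cut at each `K`.
#'
#' @param table an [indicator_table()] (expected standardized) or matrix.
#' @param K_range candidate component counts (default `1:12`).
#' @param models subset of the six covariance models (default all).
#' @param seed seed forwarded to [fit_gmm()] restarts.
#' @param ... further arguments to [fit_gmm()].
#' @return A `gmm_selection` list: `labels`, `K`, `cov_model`, `fit` (the
#'   winning `gmm_fit`), and `bic_table` (data frame `K`, `cov_model`,
#'   `BIC`, `converged`).
#' @export
select_gmm <- function(table, K_range = 1:12, models = GMM_MODELS,
                       seed = 1L, ...) {
  X <- as_values_matrix(table)
  n <- nrow(X)
  models <- match.arg(models, GMM_MODELS, several.ok = TRUE)
  K_range <- sort(unique(as.integer(K_range)))
  if (!length(K_range)) stop("K_range is empty", call. = FALSE)
  K_range <- K_range[K_range >= 1 & K_range < n]
  hc <- if (max(K_range) > 1) {
    stats::hclust(stats::dist(X), method = "ward.D2")
  } else NULL
  rows <- list()
  fits <- list()
  for (K in K_range) {
    z0 <- if (K == 1L) rep(1L, n) else stats::cutree(hc, k = K)
    for (m in models) {
      fit <- fit_gmm(X, K, m, init = z0, seed = seed, ...)
      key <- paste0(m, ":", K)
      fits[[key]] <- fit
      rows[[key]] <- data.frame(K = K, cov_model = m,
                                BIC = bic_score(fit, n),
                                converged = fit$converged &&
                                  !fit$collapsed,
                                stringsAsFactors = FALSE)
    }
  }
  bic_table <- do.call(rbind, rows)
  rownames(bic_table) <- NULL
  ok <- bic_table$converged & is.finite(bic_table$BIC)
  if (!any(ok)) stop("no Gaussian mixture fit converged", call. = FALSE)
  cand <- bic_table[ok, ]
  best_bic <- max(cand$BIC)
  tied <- cand[cand$BIC >= best_bic - 1e-9, ]
  tied <- tied[order(tied$K, match(tied$cov_model, models)), ]
  bK <- tied$K[1]; bm <- tied$cov_model[1]
  fit <- fits[[paste0(bm, ":", bK)]]
  structure(list(labels = fit$labels, K = bK, cov_model = bm, fit = fit,
                 bic_table = bic_table),
            class = "gmm_selection")
}

#' @export
print.gmm_selection <- function(x, ...) {
  cat(sprintf("Model-based clustering: best model %s with K = %d (BIC = %.2f)\n",
              x$cov_model, x$K, max(x$bic_table$BIC[x$bic_table$converged])))
  cat("cluster sizes:", paste(tabulate(x$labels, x$K), collapse = ", "), "\n")
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same units;
#' 1 means identical partitions (up to label permutation), 0 is the
#' expected agreement of random partitions.
#'
#' @param a,b integer/factor label vectors of equal length.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
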