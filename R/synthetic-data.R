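#' Configuration for the synthetic district generator
#'
#' Defines a population of districts with known latent cluster structure so
#' that every stage of the stratified-design workflow (clusterability,
#' clustering, validation, profiling, efficiency simulation) can be tested
#' against ground truth. Defaults emulate the scale of a national district
#' table: 413 districts in 31 provinces with 20 indicators.
#'
#' `separation` is the minimum Euclidean distance between cluster means in
#' units of the within-cluster standard deviation; cluster means are placed
#' at the vertices of a scaled regular simplex (when `K_true <= n_indicators`)
#' so every pairwise mean distance equals `separation`, making it a single
#' interpretable knob. Values around 4 and above give nearly
#' Bayes-separable clusters; 0 collapses all clusters onto one Gaussian.
#'
#' @param n_units number of districts (default 413).
#' @param n_provinces number of provinces (default 31).
#' @param n_indicators number of indicator columns (default 20).
#' @param K_true number of latent clusters; 0 requests a structureless null
#'   (see [generate_null()]).
#' @param separation non-negative distance between cluster means in units of
#'   within-cluster sd.
#' @param covariance_mode `"spherical"` (identity), `"diagonal"` (per-cluster
#'   random diagonal variances in `[0.5, 1.5]`) or `"full"` (random
#'   well-conditioned SPD matrices via orthogonal rotation of such spectra).
#' @param mixing_weights simplex weights of length `K_true`; default equal.
#' @param population_meanlog,population_sdlog log-normal parameters for
#'   district populations; defaults give a median near 100,000 persons with
#'   realistic heavy-tailed spread.
#' @param province_impurity fraction of districts reassigned to a random
#'   other province after the contiguous-by-cluster province blocking, so
#'   provinces straddle clusters (default 0.2).
#' @param seed RNG seed; all generation is deterministic given the seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_units = 413, n_provinces = 31,
                             n_indicators = 20, K_true = 8, separation = 5,
                             covariance_mode = c("spherical", "diagonal",
                                                 "full"),
                             mixing_weights = NULL,
                             population_meanlog = log(1e5),
                             population_sdlog = 0.7,
                             province_impurity = 0.2,
                             seed = 1L) {
  covariance_mode <- match.arg(covariance_mode)
  if (K_true < 0 || separation < 0) {
    stop("K_true and separation must be non-negative", call. = FALSE)
  }
  if (K_true > n_units) stop("n_units must be at least K_true", call. = FALSE)
  if (is.null(mixing_weights)) {
    mixing_weights <- if (K_true > 0) rep(1 / K_true, K_true) else numeric(0)
  }
  if (K_true > 0) {
    if (length(mixing_weights) != K_true ||
        abs(sum(mixing_weights) - 1) > 1e-8 || any(mixing_weights <= 0)) {
      stop("mixing_weights must be K_true positive weights summing to 1",
           call. = FALSE)
    }
  }
  structure(list(n_units = n_units, n_provinces = n_provinces,
                 n_indicators = n_indicators, K_true = K_true,
                 separation = separation, covariance_mode = covariance_mode,
                 mixing_weights = mixing_weights,
                 population_meanlog = population_meanlog,
                 population_sdlog = population_sdlog,
                 province_impurity = province_impurity,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Cluster means with all pairwise distances >= separation: scaled regular
# simplex (exact equality) when K <= d, else a 1-D lattice of spacing
# `separation` along the first coordinate. Centred to the mixing-weighted
# mean and rotated by a seeded random orthogonal matrix so the
# between-cluster signal is spread over all indicators rather than
# concentrated in K axis-aligned columns; without the rotation, column-wise
# standardization downstream would shrink exactly the signal-bearing
# columns and the separation knob would lose its meaning after
# standardization.
cluster_means <- function(K, d, separation, weights = rep(1 / K, K)) {
  if (K == 1) return(matrix(0, 1, d))
  M <- matrix(0, K, d)
  if (K <= d) {
    for (k in seq_len(K)) M[k, k] <- separation / sqrt(2)
  } else {
    M[, 1] <- separation * (seq_len(K) - 1)
  }
  M <- sweep(M, 2, colSums(M * weights), "-")
  Q <- qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
  M <- M %*% Q
  equalize_column_signal(M, weights)
}

# Rotate the mean matrix so every column carries exactly the same
# between-cluster variance (equal diagonal of B = sum_k w_k mu_k mu_k^T,
# achievable by the Schur-Horn theorem via pairwise plane rotations).
# Downstream column-wise standardization then rescales all columns by the
# same factor, preserving the mean geometry and the separation knob.
equalize_column_signal <- function(M, weights) {
  d <- ncol(M)
  if (d < 2) return(M)
  B <- crossprod(M * sqrt(weights))
  t_target <- mean(diag(B))
  for (pass in seq_len(d)) {
    dg <- diag(B)
    if (max(dg) - min(dg) < 1e-12 * max(t_target, 1e-300)) break
    i <- which.max(dg); j <- which.min(dg)
    a <- (B[i, i] - B[j, j]) / 2
    b <- B[i, j]
    R <- sqrt(a^2 + b^2)
    c0 <- t_target - (B[i, i] + B[j, j]) / 2
    c0 <- max(min(c0, R), -R)
    phi <- atan2(b, a) + acos(if (R > 0) c0 / R else 1)
    th <- phi / 2
    G <- diag(d)
    G[i, i] <- cos(th); G[j, j] <- cos(th)
    G[i, j] <- -sin(th); G[j, i] <- sin(th)
    B <- t(G) %*% B %*% G
    M <- M %*% G
  }
  M
}

random_cluster_covs <- function(K, d, mode) {
  lapply(seq_len(K), function(k) {
    if (mode == "spherical") return(diag(d))
    spectrum <- stats::runif(d, 0.5, 1.5)
    if (mode == "diagonal") return(diag(spectrum, d))
    Q <- qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
    Q %*% diag(spectrum, d) %*% t(Q)
  })
}

#' Generate a synthetic district table with latent cluster structure
#'
#' Each district is drawn from the multivariate Gaussian component of its
#' latent cluster; cluster sizes are multinomial in the mixing weights
#' (resampled if any cluster comes up empty). Provinces are formed by
#' splitting the cluster-sorted districts into `n_provinces` contiguous
#' blocks — so provinces are mostly cluster-pure — after which a fraction
#' `province_impurity` of districts is reassigned to a random other
#' province, making provinces straddle clusters as real administrative
#' units do. Populations are i.i.d. log-normal.
#'
#' @param config a [synthetic_config()] with `K_true >= 1`.
#' @return A list with `table` (an [indicator_table()], raw scale,
#'   district-native metadata) and `labels` (integer latent cluster of each
#'   unit).
#' @export
generate_districts <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$K_true < 1) {
    stop("generate_districts needs K_true >= 1; use generate_null()",
         call. = FALSE)
  }
  withr::with_seed(config$seed, generate_districts_impl(config))
}

generate_districts_impl <- function(config) {
  n <- config$n_units; d <- config$n_indicators; K <- config$K_true
  sizes <- as.vector(stats::rmultinom(1, n, config$mixing_weights))
  tries <- 0
  while (any(sizes == 0) && tries < 100) {
    sizes <- as.vector(stats::rmultinom(1, n, config$mixing_weights))
    tries <- tries + 1
  }
  if (any(sizes == 0)) { # tiny n: guarantee one unit per cluster
    sizes <- pmax(sizes, 1)
    while (sum(sizes) > n) sizes[which.max(sizes)] <- max(sizes) - 1
  }
  labels <- rep(seq_len(K), sizes)
  mu <- cluster_means(K, d, config$separation, config$mixing_weights)
  covs <- random_cluster_covs(K, d, config$covariance_mode)
  # global scale chosen so columns have unit total (within + between)
  # variance in expectation: the separation-to-within-sd ratio then
  # survives the column-wise standardization applied downstream
  between_total <- sum(config$mixing_weights * rowSums(mu^2))
  s_global <- 1 / sqrt(1 + between_total / d)
  values <- matrix(NA_real_, n, d)
  for (k in seq_len(K)) {
    idx <- which(labels == k)
    Z <- matrix(stats::rnorm(length(idx) * d), length(idx), d)
    R <- chol(covs[[k]])
    values[idx, ] <- sweep(Z %*% R, 2, mu[k, ], "+") * s_global
  }
  # units are ordered by cluster, so contiguous blocks are mostly pure
  province <- sort(rep(seq_len(config$n_provinces), length.out = n))
  if (config$province_impurity > 0 && config$n_provinces > 1) {
    n_move <- floor(config$province_impurity * n)
    movers <- sample.int(n, n_move)
    for (i in movers) {
      others <- setdiff(seq_len(config$n_provinces), province[i])
      province[i] <- others[sample.int(length(others), 1)]
    }
  }
  pop <- stats::rlnorm(n, config$population_meanlog, config$population_sdlog)
  meta <- data.frame(name = sprintf("ind%02d", seq_len(d)),
                     factor = rep(c("demand", "structure", "outcome"),
                                  length.out = d),
                     native_level = "district",
                     stringsAsFactors = FALSE)
  colnames(values) <- meta$name
  tab <- indicator_table(sprintf("D%03d", seq_len(n)),
                         sprintf("P%02d", province),
                         pop, values, meta)
  list(table = tab, labels = labels)
}

#' Generate a structureless null district table
#'
#' Two null flavours: `"uniform"` draws every indicator i.i.d. uniform on a
#' hyper-rectangle (the natural null for the Hopkins statistic, whose
#' reference points are uniform on the data's bounding box); `"gaussian"`
#' draws from a single standard multivariate Gaussian (the natural null for
#' sampling-efficiency comparisons, equivalent to [generate_districts()]
#' with one cluster).
#'
#' @param config a [synthetic_config()] with `K_true = 0`.
#' @param mode `"uniform"` or `"gaussian"`.
#' @param box numeric length-2 lower/upper bound of the uniform box
#'   (default `c(0, 1)`).
#' @return An [indicator_table()] (raw scale).
#' @export
generate_null <- function(config, mode = c("uniform", "gaussian"),
                          box = c(0, 1)) {
  stopifnot(inherits(config, "synthetic_config"))
  mode <- match.arg(mode)
  if (config$K_true != 0) {
    stop("generate_null expects K_true = 0", call. = FALSE)
  }
  if (mode == "gaussian") {
    cfg1 <- config
    cfg1$K_true <- 1L
    cfg1$mixing_weights <- 1
    cfg1$separation <- 0
    return(generate_districts(cfg1)$table)
  }
  withr::with_seed(config$seed, {
    n <- config$n_units; d <- config$n_indicators
    values <- matrix(stats::runif(n * d, box[1], box[2]), n, d)
    province <- sort(rep(seq_len(config$n_provinces), length.out = n))
    pop <- stats::rlnorm(n, config$population_meanlog, config$population_sdlog)
    meta <- data.frame(name = sprintf("ind%02d", seq_len(d)),
                       factor = rep(c("demand", "structure", "outcome"),
                                    length.out = d),
                       native_level = "district",
                       stringsAsFactors = FALSE)
    colnames(values) <- meta$name
    indicator_table(sprintf("D%03d", seq_len(n)), sprintf("P%02d", province),
                    pop, values, meta)
  })
}
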