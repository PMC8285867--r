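#' Internal and stability validity of a clustering
#'
#' Internal validity measures compactness and separation of one partition:
#' within-cluster sum of squares (lower = more compact), mean silhouette
#' width in `[-1, 1]` (higher = better matched units), and the Dunn index
#' (higher = better separated relative to cluster diameters). Stability
#' validity re-clusters the data with one indicator column removed at a
#' time and measures how much the partition moves: the average proportion
#' of non-overlap (APN), average distance (AD), average distance between
#' means (ADM) and figure of merit (FOM); for all four, smaller is more
#' stable.
#'
#' @name validity
NULL

check_partition <- function(X, labels) {
  if (length(labels) != nrow(X)) {
    stop("labels must have one entry per unit", call. = FALSE)
  }
  if (anyNA(labels)) stop("labels contain NA", call. = FALSE)
  labels
}

#' Within-cluster sum of squares
#'
#' \eqn{\sum_k \sum_{i \in C_k} \|x_i - \bar x_{C_k}\|^2}; zero for
#' all-singleton partitions, non-increasing under cluster splits.
#'
#' @param table an [indicator_table()] or numeric matrix.
#' @param labels cluster label per unit.
#' @return scalar WSS.
#' @export
within_ss <- function(table, labels) {
  X <- as_values_matrix(table)
  labels <- check_partition(X, labels)
  total <- 0
  for (k in unique(labels)) {
    Xk <- X[labels == k, , drop = FALSE]
    total <- total + sum(sweep(Xk, 2, colMeans(Xk), "-")^2)
  }
  total
}

#' Mean silhouette width
#'
#' For unit `i`, `a(i)` is its mean Euclidean dissimilarity to the other
#' members of its own cluster and `b(i)` the smallest mean dissimilarity to
#' any other cluster; `s(i) = (b - a) / max(a, b)`, with `s(i) = 0` for
#' singleton clusters. Returns the mean over all units; values near +1
#' indicate units well matched to their cluster, negative values suggest
#' misassignment.
#'
#' @inheritParams within_ss
#' @return scalar in `[-1, 1]`.
#' @export
silhouette_mean <- function(table, labels) {
  X <- as_values_matrix(table)
  labels <- check_partition(X, labels)
  ks <- unique(labels)
  if (length(ks) < 2) {
    stop("silhouette undefined for a single cluster", call. = FALSE)
  }
  D <- as.matrix(stats::dist(X))
  n <- nrow(X)
  s <- numeric(n)
  sizes <- table(labels)
  for (i in seq_len(n)) {
    own <- labels[i]
    if (sizes[as.character(own)] == 1) { s[i] <- 0; next }
    a <- sum(D[i, labels == own]) / (sizes[as.character(own)] - 1)
    b <- min(vapply(setdiff(ks, own),
                    function(k) mean(D[i, labels == k]), 0))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Dunn index
#'
#' Minimum between-cluster point distance divided by the maximum
#' within-cluster diameter; larger values indicate compact, well-separated
#' clusters. When every cluster is a singleton the maximum diameter is
#' zero and `Inf` is returned with a warning.
#'
#' @inheritParams within_ss
#' @return scalar `>= 0` (possibly `Inf` for all-singleton partitions).
#' @export
dunn_index <- function(table, labels) {
  X <- as_values_matrix(table)
  labels <- check_partition(X, labels)
  ks <- unique(labels)
  if (length(ks) < 2) stop("Dunn index needs K >= 2", call. = FALSE)
  D <- as.matrix(stats::dist(X))
  diam <- max(vapply(ks, function(k) {
    idx <- which(labels == k)
    if (length(idx) < 2) 0 else max(D[idx, idx])
  }, 0))
  sep <- min(vapply(seq_along(ks)[-1], function(i) {
    min(vapply(seq_len(i - 1), function(j) {
      min(D[labels == ks[i], labels == ks[j], drop = FALSE])
    }, 0))
  }, 0))
  if (diam == 0) {
    warning("all clusters are singletons: Dunn index is infinite",
            call. = FALSE)
    return(Inf)
  }
  sep / diam
}

#' Leave-one-column-out stability indices (APN, AD, ADM, FOM)
#'
#' For each indicator column, the data are re-clustered without that column
#' using the same method and K; the reduced-data partition is compared with
#' the full-data partition. With `C0(i)` the full-data cluster (as a set of
#' units) containing unit `i` and `Cl(i)` its cluster after deleting column
#' `l`:
#'
#' * APN: mean over (i, l) of `1 - |C0(i) ∩ Cl(i)| / |C0(i)|` — the
#'   proportion of unit i's original cluster mates it loses.
#' * AD: mean over (i, l) of the average pairwise distance between members
#'   of `C0(i)` and members of `Cl(i)`, in full-data coordinates.
#' * ADM: mean over (i, l) of the distance between the full-data centroids
#'   of `Cl(i)` and `C0(i)`.
#' * FOM: mean over l of the root mean within-cluster variance of the
#'   deleted column's values under the reduced-data partition.
#'
#' Smaller values indicate a partition that is robust to the removal of any
#' single indicator.
#'
#' @param table an [indicator_table()] or matrix (expected standardized);
#'   at least 2 columns.
#' @param method `"mcm"` (Gaussian mixture, covariance family held fixed at
#'   `cov_model` and refit on each reduced dataset) or `"hcm"`
#'   (complete-linkage cut).
#' @param K number of clusters.
#' @param cov_model covariance model for `method = "mcm"`.
#' @param seed forwarded to [fit_gmm()].
#' @param fom_adjusted apply the `sqrt(n / (n - K))` adjustment factor to
#'   FOM (default `FALSE`).
#' @param full_labels optional precomputed full-data labels (must come from
#'   the same method/K); computed when `NULL`.
#' @return list with elements `apn`, `ad`, `adm`, `fom`.
#' @export
stability_indices <- function(table, method = c("mcm", "hcm"), K,
                              cov_model = "VVV", seed = 1L,
                              fom_adjusted = FALSE, full_labels = NULL) {
  method <- match.arg(method)
  X <- as_values_matrix(table)
  n <- nrow(X); d <- ncol(X)
  if (d < 2) stop("stability indices need at least 2 columns", call. = FALSE)
  cluster_fn <- function(M) {
    if (method == "mcm") {
      fit_gmm(M, K, cov_model, seed = seed)$labels
    } else {
      cut_tree(complete_linkage(M), K)
    }
  }
  lab0 <- if (is.null(full_labels)) cluster_fn(X) else as.integer(full_labels)
  D <- as.matrix(stats::dist(X))
  cent0 <- lapply(split(seq_len(n), lab0),
                  function(idx) colMeans(X[idx, , drop = FALSE]))
  apn_terms <- c(); ad_terms <- c(); adm_terms <- c(); fom_terms <- c()
  failed <- character(0)
  for (l in seq_len(d)) {
    labl <- tryCatch(cluster_fn(X[, -l, drop = FALSE]), error = function(e) NULL)
    if (is.null(labl)) {
      failed <- c(failed, colnames(X)[l] %||% as.character(l))
      next
    }
    centl <- lapply(split(seq_len(n), labl),
                    function(idx) colMeans(X[idx, , drop = FALSE]))
    # per-unit terms depend only on the (full cluster, reduced cluster)
    # pair, so aggregate once per contingency cell
    ct <- table(lab0, labl)
    apn_l <- 0; ad_l <- 0; adm_l <- 0
    for (r in rownames(ct)) {
      C0 <- which(lab0 == as.integer(r))
      for (cc in colnames(ct)) {
        m <- ct[r, cc]
        if (m == 0) next
        Cl <- which(labl == as.integer(cc))
        apn_l <- apn_l + m * (1 - m / length(C0))
        ad_l <- ad_l + m * mean(D[C0, Cl, drop = FALSE])
        adm_l <- adm_l + m * sqrt(sum((cent0[[r]] - centl[[cc]])^2))
      }
    }
    apn_terms <- c(apn_terms, apn_l / n)
    ad_terms <- c(ad_terms, ad_l / n)
    adm_terms <- c(adm_terms, adm_l / n)
    # FOM: dispersion of the deleted column under the reduced partition
    xl <- X[, l]
    ssl <- sum(vapply(split(xl, labl), function(v) sum((v - mean(v))^2), 0))
    fom_l <- sqrt(ssl / n)
    if (fom_adjusted) fom_l <- fom_l * sqrt(n / (n - K))
    fom_terms <- c(fom_terms, fom_l)
  }
  if (!length(fom_terms)) {
    stop("re-clustering failed for every column", call. = FALSE)
  }
  if (length(failed)) {
    warning("column(s) skipped (re-clustering failed): ",
            paste(failed, collapse = ", "), call. = FALSE)
  }
  list(apn = mean(apn_terms), ad = mean(ad_terms), adm = mean(adm_terms),
       fom = mean(fom_terms))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full validity report for one clustering configuration
#'
#' Bundles the three internal indices and the four stability indices for a
#' given method and K, enabling side-by-side comparison of clustering
#' configurations (e.g. a mixture model at its BIC-selected K against
#' hierarchical cuts at the voted and at the matched K).
#'
#' @inheritParams stability_indices
#' @param labels full-data labels of the configuration under evaluation.
#' @return A `validity_report` list: `wss`, `silhouette_mean`, `dunn`,
#'   `apn`, `ad`, `adm`, `fom`, `config`.
#' @export
validity_report <- function(table, labels, method = c("mcm", "hcm"), K,
                            cov_model = "VVV", seed = 1L) {
  method <- match.arg(method)
  X <- as_values_matrix(table)
  st <- stability_indices(X, method, K, cov_model, seed,
                          full_labels = labels)
  structure(list(wss = within_ss(X, labels),
                 silhouette_mean = silhouette_mean(X, labels),
                 dunn = dunn_index(X, labels),
                 apn = st$apn, ad = st$ad, adm = st$adm, fom = st$fom,
                 config = list(method = method, K = K,
                               cov_model = if (method == "mcm") cov_model
                                           else NA_character_)),
            class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf("validity report: %s, K = %d\n", x$config$method, x$config$K))
  cat(sprintf("  internal : WSS = %.4f  silhouette = %.4f  Dunn = %.4f\n",
              x$wss, x$silhouette_mean, x$dunn))
  cat(sprintf("  stability: APN = %.4f  AD = %.4f  ADM = %.4f  FOM = %.4f\n",
              x$apn, x$ad, x$adm, x$fom))
  invisible(x)
}
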