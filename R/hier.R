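#' Agglomerative complete-linkage clustering
#'
#' Each unit starts in its own cluster and the pair of clusters at least
#' complete-linkage distance (the maximum pairwise member distance) is
#' merged at every step, producing a dendrogram whose merge heights are
#' monotone non-decreasing. Distances are Euclidean and the table is
#' expected standardized.
#'
#' @param table an [indicator_table()] or numeric matrix, `n >= 2` rows.
#' @param linkage agglomeration rule; `"complete"` (default), `"single"`
#'   and `"average"` are accepted.
#' @return An object of class `hclust` (see [stats::hclust()]), usable with
#'   [cut_tree()].
#' @export
complete_linkage <- function(table, linkage = "complete") {
  X <- as_values_matrix(table)
  if (nrow(X) < 2) stop("need at least 2 units", call. = FALSE)
  linkage <- match.arg(linkage, c("complete", "single", "average"))
  stats::hclust(stats::dist(X), method = linkage)
}

#' Cut a dendrogram into K clusters
#'
#' Undoes the last `K - 1` merges of the tree, yielding exactly `K`
#' clusters. Cuts are nested: every cluster at `K + 1` is contained in a
#' cluster at `K`.
#'
#' @param dend an `hclust` tree from [complete_linkage()].
#' @param K number of clusters, `1 <= K <= n`.
#' @return integer label vector of length `n`.
#' @export
cut_tree <- function(dend, K) {
  n <- length(dend$order)
  if (K < 1 || K > n) stop("K must be in [1, n]", call. = FALSE)
  as.integer(stats::cutree(dend, k = K))
}

#' Majority-vote proposal of the number of clusters
#'
#' Computes eight internal indices on complete-linkage cuts over `k_range`;
#' each index proposes one k and the winner is the mode (ties break to the
#' smallest k, favouring parsimony). The ensemble mirrors the
#' many-indices-majority-vote practice for choosing k in hierarchical
#' clustering, with a fixed, documented subset:
#'
#' * Calinski-Harabasz (maximize)
#' * mean silhouette width (maximize)
#' * Dunn index (maximize)
#' * Davies-Bouldin (minimize)
#' * C-index (minimize)
#' * McClain-Rao (minimize)
#' * Ball-Hall (maximize the second difference of WSS(k)/k)
#' * Hartigan (smallest k with statistic <= 10)
#'
#' An index abstains (with a message) when its value is undefined on every
#' cut, e.g. singleton-only clusterings for indices needing within-cluster
#' variance.
#'
#' @param table an [indicator_table()] or matrix (expected standardized).
#' @param k_range candidate ks, a subset of `2:(n-1)` (default `2:10`).
#' @param linkage linkage passed to [complete_linkage()].
#' @return A `k_vote` list: `k` (winning k), `votes` (named vote counts per
#'   k), `proposals` (named per-index proposed k, `NA` = abstained),
#'   `index_values` (matrix index x k).
#' @export
propose_k <- function(table, k_range = 2:10, linkage = "complete") {
  X <- as_values_matrix(table)
  n <- nrow(X)
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stop("k_range must be within [2, n-1]", call. = FALSE)
  dend <- complete_linkage(X, linkage)
  # Hartigan compares WSS(k) with WSS(k+1), so one cut above the range is
  # needed; Ball-Hall's second difference uses flanking cuts inside the
  # candidate range only (a 1-cluster cut is not a candidate clustering)
  k_ext <- sort(unique(c(k_range, max(k_range) + 1)))
  k_ext <- k_ext[k_ext >= 1 & k_ext <= n]
  cuts <- lapply(k_ext, function(k) cut_tree(dend, k))
  names(cuts) <- k_ext
  D <- as.matrix(stats::dist(X))
  wss_k <- vapply(as.character(k_ext),
                  function(k) within_ss(X, cuts[[k]]), 0)
  val <- matrix(NA_real_, 8, length(k_range),
                dimnames = list(c("calinski_harabasz", "silhouette", "dunn",
                                  "davies_bouldin", "c_index", "mcclain_rao",
                                  "ball_hall", "hartigan"),
                                as.character(k_range)))
  tss <- within_ss(X, rep(1L, n))
  for (k in k_range) {
    ck <- as.character(k)
    lab <- cuts[[ck]]
    w <- wss_k[ck]
    val["calinski_harabasz", ck] <-
      if (w > 0) ((tss - w) / (k - 1)) / (w / (n - k)) else NA_real_
    val["silhouette", ck] <- silhouette_mean(X, lab)
    val["dunn", ck] <- dunn_index(X, lab)
    val["davies_bouldin", ck] <- davies_bouldin(X, lab)
    val["c_index", ck] <- c_index(D, lab)
    val["mcclain_rao", ck] <- mcclain_rao(D, lab)
    km <- as.character(k - 1); kp <- as.character(k + 1)
    if (km %in% names(wss_k) && kp %in% names(wss_k)) {
      bh <- function(kk) wss_k[as.character(kk)] / kk
      val["ball_hall", ck] <- (bh(k - 1) - bh(k)) - (bh(k) - bh(k + 1))
    }
    if (kp %in% names(wss_k) && wss_k[kp] > 0) {
      val["hartigan", ck] <- (w / wss_k[kp] - 1) * (n - k - 1)
    }
  }
  proposals <- c(
    calinski_harabasz = arg_opt(val["calinski_harabasz", ], k_range, max),
    silhouette = arg_opt(val["silhouette", ], k_range, max),
    dunn = arg_opt(val["dunn", ], k_range, max),
    davies_bouldin = arg_opt(val["davies_bouldin", ], k_range, min),
    c_index = arg_opt(val["c_index", ], k_range, min),
    mcclain_rao = arg_opt(val["mcclain_rao", ], k_range, min),
    ball_hall = arg_opt(val["ball_hall", ], k_range, max),
    hartigan = {
      h <- val["hartigan", ]
      okh <- which(!is.na(h) & h <= 10)
      if (length(okh)) k_range[min(okh)] else NA_integer_
    })
  ab <- names(proposals)[is.na(proposals)]
  if (length(ab)) message("indices abstained: ", paste(ab, collapse = ", "))
  votes <- table(factor(proposals[!is.na(proposals)], levels = k_range))
  win <- k_range[which.max(votes)] # which.max takes first => smallest k
  structure(list(k = win, votes = votes, proposals = proposals,
                 index_values = val),
            class = "k_vote")
}

arg_opt <- function(v, k_range, opt) {
  if (all(is.na(v))) return(NA_integer_)
  target <- opt(v, na.rm = TRUE)
  k_range[which(!is.na(v) & v == target)[1]]
}

#' @export
print.k_vote <- function(x, ...) {
  cat(sprintf("Proposed number of clusters: k = %d\n", x$k))
  cat("votes:\n")
  print(x$votes)
  invisible(x)
}

davies_bouldin <- function(X, labels) {
  ks <- sort(unique(labels))
  if (length(ks) < 2) return(NA_real_)
  cent <- t(vapply(ks, function(k) colMeans(X[labels == k, , drop = FALSE]),
                   numeric(ncol(X))))
  S <- vapply(seq_along(ks), function(i) {
    Xi <- X[labels == ks[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(Xi, 2, cent[i, ], "-")^2)))
  }, 0)
  M <- cross_dist(cent, cent)
  db_k <- vapply(seq_along(ks), function(i) {
    r <- (S[i] + S[-i]) / M[i, -i]
    max(r)
  }, 0)
  mean(db_k)
}

c_index <- function(D, labels) {
  n <- nrow(D)
  iu <- which(upper.tri(D))
  dv <- D[iu]
  same <- outer(labels, labels, "==")[iu]
  nw <- sum(same)
  if (nw == 0 || nw == length(dv)) return(NA_real_)
  Sw <- sum(dv[same])
  ds <- sort(dv)
  Smin <- sum(ds[seq_len(nw)])
  Smax <- sum(ds[seq.int(length(ds) - nw + 1, length(ds))])
  if (Smax == Smin) return(NA_real_)
  (Sw - Smin) / (Smax - Smin)
}

mcclain_rao <- function(D, labels) {
  iu <- which(upper.tri(D))
  dv <- D[iu]
  same <- outer(labels, labels, "==")[iu]
  nw <- sum(same); nb <- sum(!same)
  if (nw == 0 || nb == 0) return(NA_real_)
  (sum(dv[same]) / nw) / (sum(dv[!same]) / nb)
}
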