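#' Hopkins statistic of clustering tendency
#'
#' Compares nearest-neighbour distances of `m` artificial points, drawn
#' uniformly from the per-dimension bounding box of the data, with
#' nearest-neighbour distances of `m` real points sampled without
#' replacement. With `u_j` the distance from artificial point `j` to its
#' nearest data point and `w_j` the distance from sampled real point `j` to
#' its nearest other data point,
#' \deqn{H = \sum u_j^p / (\sum u_j^p + \sum w_j^p),}
#' with exponent `p = 1` (`variant = "power1"`, the classical form) or
#' `p = d` (`variant = "powerd"`, the dimension-weighted literature
#' variant). Structureless data give `H` near 0.5; values well above 0.5
#' indicate clusterable structure (the conventional decision rule treats
#' `H > 0.5` as clusterable).
#'
#' @param table an [indicator_table()], expected standardized, or a numeric
#'   matrix.
#' @param m probe sample size, `1 <= m <= n - 1`; default
#'   `max(10, floor(0.1 n))`.
#' @param seed RNG seed for the probe draws.
#' @param variant `"power1"` (default) or `"powerd"`.
#' @return A `hopkins_result` list with elements `H`, `m`, `seed`,
#'   `variant`.
#' @export
hopkins_statistic <- function(table, m = NULL, seed = 1L,
                              variant = c("power1", "powerd")) {
  variant <- match.arg(variant)
  X <- as_values_matrix(table)
  n <- nrow(X); d <- ncol(X)
  if (is.null(m)) m <- max(10L, floor(0.1 * n))
  m <- as.integer(m)
  if (m < 1L || m > n - 1L) {
    stop("m must satisfy 1 <= m <= n_units - 1", call. = FALSE)
  }
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  withr::with_seed(as.integer(seed), {
    U <- matrix(stats::runif(m * d, rep(lo, each = m), rep(hi, each = m)),
                m, d)
    probe <- sample.int(n, m)
    u <- nn_dist_to(U, X)
    w <- nn_dist_excl(X, probe)
    p <- if (variant == "power1") 1 else d
    tot <- sum(u^p) + sum(w^p)
    if (tot == 0) {
      stop("degenerate data: all probe distances are zero", call. = FALSE)
    }
    structure(list(H = sum(u^p) / tot, m = m, seed = as.integer(seed),
                   variant = variant),
              class = "hopkins_result")
  })
}

#' @export
print.hopkins_result <- function(x, ...) {
  cat(sprintf("Hopkins statistic H = %.4f (m = %d, %s)\n", x$H, x$m,
              x$variant))
  cat(if (x$H > 0.5) "H > 0.5: data show clustering tendency\n"
      else "H <= 0.5: no evidence of clustering tendency\n")
  invisible(x)
}

as_values_matrix <- function(table) {
  if (inherits(table, "indicator_table")) table$values
  else as.matrix(table)
}

# nearest-neighbour distance from each row of A to any row of X
nn_dist_to <- function(A, X) {
  D <- cross_dist(A, X)
  apply(D, 1, min)
}

# nearest-neighbour distance from each indexed row of X to the rest of X
nn_dist_excl <- function(X, idx) {
  D <- cross_dist(X[idx, , drop = FALSE], X)
  for (j in seq_along(idx)) D[j, idx[j]] <- Inf
  apply(D, 1, min)
}

# Euclidean cross-distance matrix between rows of A (m x d) and B (n x d)
cross_dist <- function(A, B) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  D2 <- outer(a2, b2, "+") - 2 * A %*% t(B)
  sqrt(pmax(D2, 0))
}
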