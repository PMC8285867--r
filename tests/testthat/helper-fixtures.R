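# Shared fixtures, built in code at test time.

# minimal hand-sized table: 4 districts in 2 provinces, 2 indicators
toy_table <- function(values = cbind(a = c(0, 1, 10, 11),
                                     b = c(0, 0, 0, 0)),
                      population = c(100, 300, 200, 400),
                      province = c("P1", "P1", "P2", "P2")) {
  meta <- data.frame(name = colnames(values),
                     factor = c("demand", "outcome")[seq_len(ncol(values))],
                     native_level = "district",
                     stringsAsFactors = FALSE)
  indicator_table(sprintf("D%03d", seq_len(nrow(values))), province,
                  population, values, meta)
}

# write a small CSV + metadata YAML, return both paths
write_toy_csv <- function(dir, rows, meta) {
  csv <- file.path(dir, "table.csv")
  writeLines(rows, csv)
  yml <- file.path(dir, "meta.yaml")
  yaml::write_yaml(meta, yml)
  list(csv = csv, meta = yml)
}

default_meta_yaml <- function(names, level = "district") {
  y <- lapply(names, function(n) list(factor = "outcome",
                                      native_level = level))
  names(y) <- names
  y
}

# brute-force oracles: direct transcription of the index definitions,
# kept independent of the package implementations
oracle_wss <- function(X, labels) {
  s <- 0
  for (k in unique(labels)) {
    idx <- which(labels == k)
    cen <- colMeans(X[idx, , drop = FALSE])
    for (i in idx) s <- s + sum((X[i, ] - cen)^2)
  }
  s
}

oracle_silhouette <- function(X, labels) {
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(vapply(own, function(j) d(i, j), 0))
    b <- Inf
    for (k in setdiff(unique(labels), labels[i])) {
      mem <- which(labels == k)
      b <- min(b, mean(vapply(mem, function(j) d(i, j), 0)))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

oracle_dunn <- function(X, labels) {
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  ks <- unique(labels)
  diam <- 0; sep <- Inf
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (labels[i] == labels[j]) diam <- max(diam, d(i, j))
    else sep <- min(sep, d(i, j))
  }
  if (diam == 0) Inf else sep / diam
}

oracle_hopkins <- function(X, U, probe_idx, p = 1) {
  d <- function(a, b) sqrt(sum((a - b)^2))
  u <- apply(U, 1, function(a) min(apply(X, 1, function(b) d(a, b))))
  w <- vapply(seq_along(probe_idx), function(j) {
    i <- probe_idx[j]
    min(apply(X[-i, , drop = FALSE], 1, function(b) d(X[i, ], b)))
  }, 0)
  sum(u^p) / (sum(u^p) + sum(w^p))
}

random_instance <- function(seed) {
  withr::with_seed(seed, {
    n <- sample(4:12, 1)
    d <- sample(1:3, 1)
    K <- sample(2:min(4, n - 1), 1)
    X <- matrix(rnorm(n * d), n, d)
    labels <- c(seq_len(K), sample.int(K, n - K, replace = TRUE))
    list(X = X, labels = labels, n = n, d = d, K = K)
  })
}
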