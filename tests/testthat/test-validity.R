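test_that("hand-computed values on the 1-D toy partition", {
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  lab <- c(1, 1, 2, 2)
  expect_equal(within_ss(X, lab), 1.0)
  # outer points (0, 11): a = 1, b = 10.5 -> s = 9.5/10.5;
  # inner points (1, 10): a = 1, b = 9.5 -> s = 8.5/9.5
  expect_equal(silhouette_mean(X, lab),
               mean(c(9.5 / 10.5, 8.5 / 9.5, 8.5 / 9.5, 9.5 / 10.5)),
               tolerance = 1e-10)
  expect_equal(dunn_index(X, lab), 9)
})

test_that("internal indices match brute-force oracles on random instances", {
  worst <- 0
  for (s in 1:200) {
    inst <- random_instance(s)
    w <- abs(within_ss(inst$X, inst$labels) -
             oracle_wss(inst$X, inst$labels))
    si <- abs(silhouette_mean(inst$X, inst$labels) -
              oracle_silhouette(inst$X, inst$labels))
    du_pkg <- dunn_index(inst$X, inst$labels)
    du_or <- oracle_dunn(inst$X, inst$labels)
    du <- if (is.infinite(du_pkg) && is.infinite(du_or)) 0
          else abs(du_pkg - du_or)
    worst <- max(worst, w, si, du)
  }
  expect_lt(worst, 1e-10)
})

test_that("silhouette agrees with the cluster package", {
  skip_if_not_installed("cluster")
  for (s in 1:20) {
    inst <- random_instance(500 + s)
    sil <- cluster::silhouette(inst$labels, stats::dist(inst$X))
    expect_equal(silhouette_mean(inst$X, inst$labels),
                 mean(sil[, "sil_width"]), tolerance = 1e-10)
  }
})

test_that("degenerate partitions behave as documented", {
  withr::with_seed(7, X <- matrix(rnorm(12), 6, 2))
  expect_equal(within_ss(X, 1:6), 0) # all singletons
  expect_warning(d <- dunn_index(X, 1:6), "singleton")
  expect_true(is.infinite(d))
  expect_error(silhouette_mean(X, rep(1, 6)), "single cluster")
  # merging two clusters never decreases WSS
  lab3 <- c(1, 1, 2, 2, 3, 3)
  lab2 <- c(1, 1, 2, 2, 2, 2)
  expect_gte(within_ss(X, lab2), within_ss(X, lab3) - 1e-12)
  # zero inter-cluster distance: the two clusters share a duplicated point
  Xd <- rbind(X[1:2, ], X[2, , drop = FALSE], X[3, , drop = FALSE])
  expect_equal(dunn_index(Xd, c(1, 1, 2, 2))[[1]], 0)
  # scaling leaves Dunn unchanged
  lab <- c(1, 1, 1, 2, 2, 2)
  expect_equal(dunn_index(X, lab), dunn_index(7 * X, lab), tolerance = 1e-12)
})

test_that("any single swap away from the separable partition lowers mean silhouette", {
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  best <- silhouette_mean(X, c(1, 1, 2, 2))
  for (i in 1:4) {
    lab <- c(1, 1, 2, 2)
    lab[i] <- 3 - lab[i]
    expect_lt(silhouette_mean(X, lab), best)
  }
})

test_that("perfect compactness gives mean silhouette 1", {
  X <- rbind(matrix(0, 4, 2), matrix(5, 4, 2))
  expect_equal(silhouette_mean(X, rep(1:2, each = 4)), 1)
})

test_that("indices are invariant to unit reordering and label permutation", {
  inst <- random_instance(99)
  perm <- withr::with_seed(2, sample.int(inst$n))
  relab <- max(inst$labels) + 1 - inst$labels
  expect_equal(within_ss(inst$X[perm, ], inst$labels[perm]),
               within_ss(inst$X, inst$labels), tolerance = 1e-12)
  expect_equal(silhouette_mean(inst$X, relab),
               silhouette_mean(inst$X, inst$labels), tolerance = 1e-12)
  expect_equal(dunn_index(inst$X[perm, ], relab[perm]),
               dunn_index(inst$X, inst$labels), tolerance = 1e-12)
})

test_that("duplicated columns give APN = 0 and ADM = 0; constant column FOM = 0", {
  # each column duplicated: removing one leaves the geometry unchanged,
  # so the partition cannot move
  gen <- generate_districts(synthetic_config(n_units = 60, n_indicators = 3,
                                             K_true = 2, separation = 10,
                                             seed = 33))
  X <- standardize(gen$table)$values
  Xdup <- cbind(X, X)
  colnames(Xdup) <- paste0("c", 1:6)
  st <- stability_indices(Xdup, method = "hcm", K = 2)
  expect_equal(st$apn, 0)
  expect_equal(st$adm, 0)
  expect_gt(st$ad, 0) # AD measures spread, not disagreement

  # FOM contribution of a constant column is exactly zero
  Xc <- cbind(X, const = 0)
  stc <- stability_indices(Xc, method = "hcm", K = 2)
  # removing any non-constant column: FOM over remaining columns; the
  # constant column's own dispersion term is 0, so mean FOM with the
  # constant column present is (d/(d+1)) of the pairwise-only value
  # computed over non-constant deletions -- check the direct contribution:
  fom_const <- local({
    labl <- cut_tree(complete_linkage(Xc[, -4]), 2)
    v <- Xc[, 4]
    sqrt(sum(vapply(split(v, labl),
                    function(g) sum((g - mean(g))^2), 0)) / length(v))
  })
  expect_equal(fom_const, 0)
  expect_true(all(vapply(stc, is.finite, TRUE)))
})

test_that("stability indices stay in range and are small for strong structure", {
  for (s in 1:5) {
    gen <- generate_districts(synthetic_config(K_true = 8, separation = 6,
                                               seed = s))
    st <- stability_indices(standardize(gen$table), method = "mcm", K = 8,
                            cov_model = "EII", seed = s)
    expect_gte(st$apn, 0); expect_lte(st$apn, 1)
    expect_gte(st$ad, 0); expect_gte(st$adm, 0); expect_gte(st$fom, 0)
    expect_lt(st$apn, 0.05)
  }
})

test_that("validity_report bundles internal and stability indices", {
  gen <- generate_districts(synthetic_config(n_units = 80, n_indicators = 4,
                                             K_true = 2, separation = 6,
                                             seed = 55))
  tab <- standardize(gen$table)
  lab <- cut_tree(complete_linkage(tab), 2)
  rep <- validity_report(tab, lab, method = "hcm", K = 2)
  expect_s3_class(rep, "validity_report")
  expect_gte(rep$silhouette_mean, -1); expect_lte(rep$silhouette_mean, 1)
  expect_gte(rep$dunn, 0)
  expect_equal(rep$wss, within_ss(tab, lab))
  expect_equal(rep$config$method, "hcm")
})
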