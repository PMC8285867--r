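test_that("province assignment follows majority and weighted population", {
  # both criteria agree
  tab <- toy_table(province = c("P1", "P1", "P1", "P2"))
  pa <- assign_provinces(tab, c(1, 1, 1, 2))
  expect_equal(unname(pa$assignment["P1"]), "1")
  expect_false(pa$diagnostics$conflict[pa$diagnostics$province_id == "P1"])

  # majority says A, population says B -> B with conflict flag
  meta <- data.frame(name = "x", factor = "demand",
                     native_level = "district")
  tab2 <- indicator_table(paste0("D", 1:3), rep("P1", 3),
                          c(100, 100, 700), cbind(x = c(0, 0, 5)), meta)
  pa2 <- assign_provinces(tab2, c(1, 1, 2))
  expect_equal(unname(pa2$assignment["P1"]), "2")
  expect_true(pa2$diagnostics$conflict)

  # province entirely in one cluster
  pa3 <- assign_provinces(tab2, c(2, 2, 2))
  expect_equal(unname(pa3$assignment["P1"]), "2")
  expect_false(pa3$diagnostics$conflict)
})

test_that("medoid province minimizes total distance to cluster peers", {
  meta <- data.frame(name = "x", factor = "demand",
                     native_level = "district")
  # three single-district provinces with 1-D features 0, 1, 5
  tab <- indicator_table(paste0("D", 1:3), c("PA", "PB", "PC"),
                         rep(10, 3), cbind(x = c(0, 1, 5)), meta)
  pa <- assign_provinces(tab, rep(1, 3))
  expect_equal(medoid_province(pa, tab, 1), "PB") # total 5 vs 6 and 9

  # single-province cluster returns itself
  tab1 <- indicator_table(c("D1", "D2"), c("PA", "PB"), c(10, 10),
                          cbind(x = c(0, 9)), meta)
  pa1 <- assign_provinces(tab1, c(1, 2))
  expect_equal(medoid_province(pa1, tab1, 2), "PB")

  # two-province cluster: tie broken to the smaller province id
  tab2 <- indicator_table(c("D1", "D2"), c("PB", "PA"), c(10, 10),
                          cbind(x = c(0, 9)), meta)
  pa2 <- assign_provinces(tab2, c(1, 1))
  expect_equal(medoid_province(pa2, tab2, 1), "PA")

  expect_error(medoid_province(pa1, tab1, 99), "no province")
})

test_that("province features are population-weighted district means", {
  meta <- data.frame(name = "x", factor = "demand",
                     native_level = "district")
  tab <- indicator_table(c("D1", "D2"), c("P1", "P1"), c(100, 300),
                         cbind(x = c(10, 20)), meta)
  expect_equal(unname(province_features(tab)["P1", "x"]), 17.5)
})

test_that("population-weighted mean obeys its arithmetic and convexity", {
  expect_equal(weighted_mean_pop(c(10, 20), c(100, 300)), 17.5)
  expect_equal(weighted_mean_pop(c(3, 9), c(50, 50)), 6) # equal weights
  withr::with_seed(61, {
    for (i in 1:20) {
      v <- rnorm(5); p <- runif(5, 1, 100)
      wm <- weighted_mean_pop(v, p)
      expect_gte(wm, min(v)); expect_lte(wm, max(v))
    }
  })
  expect_error(weighted_mean_pop(numeric(0), numeric(0)), "empty")
})

test_that("efficiency simulation is deterministic and correctly shaped", {
  gen <- generate_districts(synthetic_config(n_units = 80, n_indicators = 4,
                                             K_true = 4, separation = 4,
                                             seed = 5))
  e1 <- simulate_efficiency(gen$table, gen$labels, B = 100, seed = 9)
  e2 <- simulate_efficiency(gen$table, gen$labels, B = 100, seed = 9)
  expect_identical(e1, e2)
  expect_equal(e1$n_sampled, 4)
  expect_equal(nrow(e1$summary), 4)
  expect_true(all(e1$summary$efficiency > 0 | e1$summary$degenerate))
  e3 <- simulate_efficiency(gen$table, gen$labels, B = 100, seed = 10)
  expect_false(identical(e1$summary, e3$summary))
  expect_error(simulate_efficiency(gen$table, rep(1, 80), B = 10),
               "2 clusters")
  expect_error(simulate_efficiency(gen$table, gen$labels, B = 1), "B >= 2")
  expect_error(simulate_efficiency(gen$table, gen$labels,
                                   indicators = "nope", B = 10), "nope")
})

test_that("within-cluster-constant indicator with equal populations is flagged degenerate", {
  meta <- data.frame(name = c("flat", "noisy"), factor = "outcome",
                     native_level = "district")
  withr::with_seed(71, noisy <- rnorm(12))
  lab <- rep(1:3, each = 4)
  vals <- cbind(flat = c(1, 1, 1, 1, 5, 5, 5, 5, 9, 9, 9, 9), noisy = noisy)
  tab <- indicator_table(paste0("D", 1:12), rep("P1", 12), rep(100, 12),
                         vals, meta)
  eff <- simulate_efficiency(tab, lab, B = 50, seed = 3)
  flat <- eff$summary[eff$summary$indicator == "flat", ]
  expect_true(flat$degenerate)
  expect_true(is.na(flat$efficiency))
  expect_equal(flat$var_cluster, 0)
  expect_false(eff$summary$degenerate[eff$summary$indicator == "noisy"])
})

test_that("cluster and SRS estimates target the same functional on null data", {
  nul <- generate_null(synthetic_config(n_units = 200, n_indicators = 2,
                                        K_true = 0, seed = 15),
                       mode = "gaussian")
  lab <- rep(1:4, each = 50) # arbitrary equal-size partition
  eff <- simulate_efficiency(nul, lab, B = 2000, seed = 15)
  s <- eff$summary
  # both designs estimate the same population quantity: means agree within
  # 3 Monte-Carlo standard errors
  se <- sqrt(s$var_srs / eff$B + s$var_cluster / eff$B)
  expect_true(all(abs(s$mean_srs - s$mean_cluster) < 3 * se))
})

test_that("structureless null gives efficiency near 1; strong structure well above 1", {
  ok_null <- 0
  for (s in 1:10) {
    nul <- generate_null(synthetic_config(n_units = 200, n_indicators = 3,
                                          K_true = 0, seed = 400 + s),
                         mode = "gaussian")
    lab <- rep(1:4, each = 50)
    eff <- simulate_efficiency(nul, lab, B = 1000, seed = s)
    if (all(eff$summary$efficiency > 0.8 & eff$summary$efficiency < 1.25)) {
      ok_null <- ok_null + 1
    }
  }
  expect_gte(ok_null, 9)

  # between-cluster variance >= 5x within-cluster variance
  ok_str <- 0
  for (s in 1:10) {
    gen <- generate_districts(synthetic_config(n_units = 200,
                                               n_indicators = 3,
                                               K_true = 4, separation = 7,
                                               seed = 500 + s))
    eff <- simulate_efficiency(gen$table, gen$labels, B = 1000, seed = s)
    X <- gen$table$values
    bv <- apply(X, 2, function(v) var(tapply(v, gen$labels, mean)))
    wv <- apply(X, 2, function(v) mean(tapply(v, gen$labels, var)))
    strong <- which(bv >= 5 * wv)
    if (length(strong) &&
        all(eff$summary$efficiency[strong] > 1.3)) ok_str <- ok_str + 1
  }
  expect_gte(ok_str, 9)
})
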