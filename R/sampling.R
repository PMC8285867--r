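#' Province assignment, medoid provinces and sampling-efficiency simulation
#'
#' Clusters are built from districts, but field logistics operate at the
#' province level. A province is assigned to the cluster in which both the
#' majority of its districts and the largest share of its district
#' population fall; when the two criteria disagree, the weighted-population
#' criterion decides and the province is flagged. The cluster's
#' representative sampling site is its medoid province: the one minimizing
#' the total distance to the other provinces of the same cluster, each
#' province represented by the population-weighted mean of its districts'
#' standardized indicators.
#'
#' @name sampling_sim
NULL

#' Assign provinces to clusters by district majority and weighted population
#'
#' @param table an [indicator_table()].
#' @param labels cluster label per district.
#' @return A `province_assignment` list: `assignment` (named vector,
#'   province -> cluster) and `diagnostics` (data frame with per-province
#'   district counts, population by winning cluster and `conflict` flag).
#' @export
assign_provinces <- function(table, labels) {
  stopifnot(inherits(table, "indicator_table"))
  labels <- check_partition(table$values, labels)
  provs <- unique(table$province_id)
  rows <- lapply(provs, function(p) {
    idx <- which(table$province_id == p)
    counts <- tapply(rep(1, length(idx)), labels[idx], sum)
    pops <- tapply(table$population[idx], labels[idx], sum)
    by_count <- names(counts)[which.max(counts)]
    by_pop <- names(pops)[which.max(pops)]
    conflict <- by_count != by_pop
    data.frame(province_id = p,
               cluster = by_pop, # weighted population decides on conflict
               n_districts = length(idx),
               majority_cluster = by_count,
               population_cluster = by_pop,
               conflict = conflict,
               stringsAsFactors = FALSE)
  })
  diag <- do.call(rbind, rows)
  assignment <- stats::setNames(diag$cluster, diag$province_id)
  structure(list(assignment = assignment, diagnostics = diag),
            class = "province_assignment")
}

#' Province feature vectors: population-weighted means of district values
#'
#' @param table an [indicator_table()] (expected standardized).
#' @return matrix, provinces x indicators, rownames = province ids.
#' @export
province_features <- function(table) {
  stopifnot(inherits(table, "indicator_table"))
  provs <- unique(table$province_id)
  d <- ncol(table$values)
  out <- matrix(NA_real_, length(provs), d,
                dimnames = list(provs, colnames(table$values)))
  for (i in seq_along(provs)) {
    idx <- which(table$province_id == provs[i])
    w <- table$population[idx] / sum(table$population[idx])
    out[i, ] <- colSums(table$values[idx, , drop = FALSE] * w)
  }
  out
}

#' Medoid province of a cluster
#'
#' Among the provinces assigned to `cluster`, returns the one whose total
#' Euclidean distance to the other same-cluster provinces is smallest (the
#' representative province to sample from). A single-province cluster
#' returns that province; exact ties break to the lexicographically
#' smallest province id.
#'
#' @param assignment a `province_assignment` from [assign_provinces()].
#' @param table the [indicator_table()] the assignment was built from
#'   (expected standardized).
#' @param cluster cluster label.
#' @return the medoid `province_id`.
#' @export
medoid_province <- function(assignment, table, cluster) {
  stopifnot(inherits(assignment, "province_assignment"))
  members <- names(assignment$assignment)[
    assignment$assignment == as.character(cluster)]
  if (!length(members)) {
    stop("no province assigned to cluster ", cluster, call. = FALSE)
  }
  members <- sort(members)
  if (length(members) == 1L) return(members)
  F <- province_features(table)[members, , drop = FALSE]
  D <- as.matrix(stats::dist(F))
  tot <- rowSums(D)
  members[which.min(tot)] # ties: first of the sorted ids
}

#' Population-weighted mean of selected units
#'
#' \eqn{\sum_i w_i x_i} with \eqn{w_i = pop_i / \sum_j pop_j}, the weights
#' proportional to each selected district's share of the selected
#' districts' total population.
#'
#' @param values numeric vector of indicator values.
#' @param populations positive populations, same length.
#' @return scalar weighted mean.
#' @export
weighted_mean_pop <- function(values, populations) {
  if (!length(values)) stop("empty selection", call. = FALSE)
  stopifnot(length(values) == length(populations), all(populations > 0))
  sum(values * populations / sum(populations))
}

#' Monte-Carlo sampling-efficiency comparison: cluster-stratified vs SRS
#'
#' In each of `B` replicates, the cluster-stratified design draws one
#' district uniformly at random from every cluster, and the SRS design
#' draws the same number of districts without replacement from all
#' districts. Each design's estimate is the population-weighted mean of
#' each indicator over its selected districts (raw scale). After `B`
#' replicates, the sampling efficiency of the stratified design for an
#' indicator is
#' \deqn{eff = Var_{SRS}(\bar X) / Var_{cluster}(\bar X)}
#' (sample variances across replicates, denominator `B - 1`); values above
#' 1 mean the stratified design estimates that indicator more precisely.
#' An indicator whose cluster-design estimate never varies has
#' `var_cluster = 0` and its efficiency is reported as `NA` with a
#' `degenerate` flag rather than as infinite.
#'
#' @param table an [indicator_table()]; raw-scale values are used.
#' @param labels cluster label per district, `K >= 2` clusters.
#' @param indicators indicator names to evaluate (default all).
#' @param B replicate count (default 1000).
#' @param seed RNG seed; the report is bit-identical given the seed.
#' @param weight_within `"uniform"` (default) draws within a cluster
#'   uniformly; `"population"` draws proportional to district population.
#' @return An `efficiency_report` list: `summary` (data frame `indicator`,
#'   `mean_srs`, `mean_cluster`, `var_srs`, `var_cluster`, `efficiency`,
#'   `degenerate`), `B`, `seed`, `n_sampled`.
#' @export
simulate_efficiency <- function(table, labels, indicators = NULL, B = 1000,
                                seed = 1L,
                                weight_within = c("uniform", "population")) {
  stopifnot(inherits(table, "indicator_table"))
  weight_within <- match.arg(weight_within)
  labels <- check_partition(table$values, labels)
  ks <- sort(unique(labels))
  K <- length(ks)
  if (K < 2) stop("need at least 2 clusters", call. = FALSE)
  if (B < 2) stop("need B >= 2 replicates", call. = FALSE)
  if (is.null(indicators)) indicators <- colnames(table$values)
  missing_ind <- setdiff(indicators, colnames(table$values))
  if (length(missing_ind)) {
    stop("unknown indicator(s): ", paste(missing_ind, collapse = ", "),
         call. = FALSE)
  }
  X <- table$values[, indicators, drop = FALSE]
  pop <- table$population
  n <- nrow(X)
  idx_by_k <- lapply(ks, function(k) which(labels == k))
  est <- withr::with_seed(as.integer(seed), {
    cl_est <- matrix(NA_real_, B, length(indicators))
    srs_est <- matrix(NA_real_, B, length(indicators))
    for (b in seq_len(B)) {
      sel_cl <- vapply(idx_by_k, function(idx) {
        if (length(idx) == 1L) return(idx)
        if (weight_within == "uniform") idx[sample.int(length(idx), 1)]
        else idx[sample.int(length(idx), 1, prob = pop[idx])]
      }, 0L)
      sel_srs <- sample.int(n, K)
      w_cl <- pop[sel_cl] / sum(pop[sel_cl])
      w_srs <- pop[sel_srs] / sum(pop[sel_srs])
      cl_est[b, ] <- colSums(X[sel_cl, , drop = FALSE] * w_cl)
      srs_est[b, ] <- colSums(X[sel_srs, , drop = FALSE] * w_srs)
    }
    list(cl = cl_est, srs = srs_est)
  })
  var_cl <- apply(est$cl, 2, stats::var)
  var_srs <- apply(est$srs, 2, stats::var)
  degenerate <- var_cl == 0
  eff <- ifelse(degenerate, NA_real_, var_srs / var_cl)
  summary <- data.frame(indicator = indicators,
                        mean_srs = colMeans(est$srs),
                        mean_cluster = colMeans(est$cl),
                        var_srs = var_srs, var_cluster = var_cl,
                        efficiency = eff, degenerate = degenerate,
                        stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  structure(list(summary = summary, B = as.integer(B),
                 seed = as.integer(seed), n_sampled = K),
            class = "efficiency_report")
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(sprintf("sampling efficiency over B = %d replicates (%d units/replicate)\n",
              x$B, x$n_sampled))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    if (s$degenerate[i]) {
      cat(sprintf("  %-16s var_cluster = 0 (degenerate; efficiency undefined)\n",
                  s$indicator[i]))
    } else {
      cat(sprintf("  %-16s efficiency = %.3f (var_srs %.4g / var_cluster %.4g)\n",
                  s$indicator[i], s$efficiency[i], s$var_srs[i],
                  s$var_cluster[i]))
    }
  }
  invisible(x)
}
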