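#' End-to-end stratified-design workflow
#'
#' Runs the full design pipeline on one indicator table: clustering
#' tendency (Hopkins), model-based clustering with BIC selection,
#' complete-linkage clustering with the k-vote ensemble, a three-way
#' validity comparison (mixture at its BIC-selected K, hierarchical at the
#' voted k, hierarchical at the mixture's K), selection of the working
#' clustering, decision-tree profiling, province assignment with medoid
#' provinces, and the sampling-efficiency simulation. All artifacts are
#' written under `out_dir` as CSV/JSON together with a manifest of seeds,
#' configuration and output checksums; identical inputs, configuration and
#' seeds yield bit-identical outputs.
#'
#' @param table an [indicator_table()] with raw values (it is standardized
#'   internally unless `standardize = FALSE`), or a CSV path.
#' @param meta indicator metadata (when `table` is a path).
#' @param out_dir output directory (created if needed).
#' @param standardize standardize indicators before distance-based stages
#'   (default `TRUE`).
#' @param K_range,models mixture search grid (see [select_gmm()]).
#' @param k_range hierarchical k-vote range (see [propose_k()]).
#' @param tree_max_depth,tree_min_leaf profiling-tree controls.
#' @param B efficiency-simulation replicates.
#' @param seed master seed; stage seeds derive from it and are recorded.
#' @param selection `"auto"` picks the configuration winning the majority
#'   of the seven validity indices (ties favour the mixture clustering);
#'   `"mcm"` or `"hcm"` force a method. The automated rule is a documented
#'   default — in practice the final call typically also involves expert
#'   review of the strata.
#' @return A `pipeline_result` list: `hopkins`, `mcm` (selection),
#'   `k_vote`, `validity` (list of three `validity_report`s), `selected`
#'   (method, K, labels), `rules`, `feature_ranking`, `provinces`,
#'   `medoids`, `efficiency`, `manifest`.
#' @export
run_pipeline <- function(table, meta = NULL, out_dir = NULL,
                         standardize = TRUE, K_range = 1:12,
                         models = GMM_MODELS, k_range = 2:10,
                         tree_max_depth = 6, tree_min_leaf = 5,
                         B = 1000, seed = 1L,
                         selection = c("auto", "mcm", "hcm")) {
  selection <- match.arg(selection)
  if (is.character(table)) {
    if (is.null(meta)) stop("meta is required when table is a path",
                            call. = FALSE)
    table <- read_indicator_table(table, meta)
    table <- broadcast_province_values(table)
  }
  stopifnot(inherits(table, "indicator_table"))
  if (anyNA(table$values)) {
    stop("table has missing values: broadcast_province_values() first",
         call. = FALSE)
  }
  raw <- table
  std <- if (standardize) standardize(table) else table
  seed <- as.integer(seed)

  hop <- hopkins_statistic(std, seed = seed)
  mcm <- select_gmm(std, K_range = K_range, models = models, seed = seed)
  kv <- propose_k(std, k_range = k_range)
  dend <- complete_linkage(std)

  configs <- list(
    mcm_best = list(method = "mcm", K = mcm$K, labels = mcm$labels,
                    cov_model = mcm$cov_model),
    hcm_vote = list(method = "hcm", K = kv$k,
                    labels = cut_tree(dend, kv$k), cov_model = NA),
    hcm_at_mcm_k = list(method = "hcm", K = mcm$K,
                        labels = cut_tree(dend, mcm$K), cov_model = NA))
  if (mcm$K == kv$k) configs$hcm_at_mcm_k <- NULL
  validity <- lapply(configs, function(cf) {
    validity_report(std, cf$labels, method = cf$method, K = cf$K,
                    cov_model = if (cf$method == "mcm") cf$cov_model
                                else "VVV",
                    seed = seed)
  })

  sel_name <- switch(selection,
                     auto = select_by_indices(validity),
                     mcm = "mcm_best",
                     hcm = "hcm_vote")
  sel <- configs[[sel_name]]

  tree <- fit_tree(raw, sel$labels, max_depth = tree_max_depth,
                   min_leaf = tree_min_leaf)
  rules <- extract_rules(tree)
  ranking <- rank_features(tree)

  provs <- assign_provinces(std, sel$labels)
  clusters <- sort(unique(provs$assignment))
  medoids <- vapply(clusters, function(k) medoid_province(provs, std, k), "")

  eff <- simulate_efficiency(raw, sel$labels, B = B, seed = seed + 1L)

  result <- structure(
    list(hopkins = hop, mcm = mcm, k_vote = kv, validity = validity,
         selected = list(config = sel_name, method = sel$method, K = sel$K,
                         labels = sel$labels),
         rules = rules, feature_ranking = ranking, provinces = provs,
         medoids = medoids, efficiency = eff,
         manifest = NULL),
    class = "pipeline_result")

  if (!is.null(out_dir)) {
    result$manifest <- write_pipeline_outputs(result, raw, out_dir,
                                              seed = seed, B = B)
  }
  result
}

# majority across the seven validity indices; ties go to the mixture model
select_by_indices <- function(validity) {
  score <- function(get, better) {
    v <- vapply(validity, get, 0)
    names(validity)[if (better == "min") which.min(v) else which.max(v)]
  }
  wins <- c(score(function(r) r$wss, "min"),
            score(function(r) r$silhouette_mean, "max"),
            score(function(r) r$dunn, "max"),
            score(function(r) r$apn, "min"),
            score(function(r) r$ad, "min"),
            score(function(r) r$adm, "min"),
            score(function(r) r$fom, "min"))
  tab <- table(factor(wins, levels = names(validity)))
  best <- names(tab)[tab == max(tab)]
  if ("mcm_best" %in% best) "mcm_best" else best[1]
}

write_pipeline_outputs <- function(result, raw, out_dir, seed, B) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  labels_df <- data.frame(unit_id = raw$unit_id,
                          province_id = raw$province_id,
                          cluster = result$selected$labels,
                          stringsAsFactors = FALSE)
  utils::write.csv(labels_df, p("labels.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(result$mcm$bic_table, p("bic.csv"), row.names = FALSE,
                   quote = FALSE)
  kv_df <- data.frame(index = names(result$k_vote$proposals),
                      proposed_k = unname(result$k_vote$proposals))
  utils::write.csv(kv_df, p("k_vote.csv"), row.names = FALSE, quote = FALSE)
  val <- lapply(result$validity, function(r) {
    r[c("wss", "silhouette_mean", "dunn", "apn", "ad", "adm", "fom")]
  })
  jsonlite::write_json(
    list(hopkins = result$hopkins$H, validity = val,
         selected = result$selected[c("config", "method", "K")],
         medoids = as.list(result$medoids)),
    p("report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  rules_json <- lapply(result$rules$rules, function(r) {
    list(conditions = r$conditions, cluster = r$cluster,
         n_covered = r$n_covered, n_correct = r$n_correct)
  })
  jsonlite::write_json(list(rules = rules_json,
                            overall_accuracy = result$rules$overall_accuracy),
                       p("rules.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.csv(result$feature_ranking, p("feature_ranking.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(result$provinces$diagnostics, p("provinces.csv"),
                   row.names = FALSE, quote = FALSE)
  eff <- result$efficiency$summary
  eff$flag <- ifelse(eff$degenerate, "undefined", "ok")
  utils::write.csv(eff, p("efficiency.csv"), row.names = FALSE,
                   quote = FALSE)
  files <- c("labels.csv", "bic.csv", "k_vote.csv", "report.json",
             "rules.json", "feature_ranking.csv", "provinces.csv",
             "efficiency.csv")
  manifest <- list(
    package = "strataminer",
    version = as.character(utils::packageVersion("strataminer")),
    seed = seed, B = B,
    checksums = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("stratified-design pipeline result\n")
  cat(sprintf("  Hopkins H = %.3f\n", x$hopkins$H))
  cat(sprintf("  mixture clustering: %s, K = %d\n", x$mcm$cov_model, x$mcm$K))
  cat(sprintf("  hierarchical k-vote: k = %d\n", x$k_vote$k))
  cat(sprintf("  selected: %s (K = %d)\n", x$selected$config, x$selected$K))
  cat(sprintf("  %d partitioning rules, accuracy %.3f\n",
              length(x$rules$rules), x$rules$overall_accuracy))
  cat(sprintf("  medoid provinces: %s\n",
              paste(x$medoids, collapse = ", ")))
  invisible(x)
}
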