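#' Describe clusters as decision-tree partitioning rules
#'
#' A classification tree is grown on the raw-scale indicators with the
#' cluster labels as the response; each root-to-leaf path becomes a
#' human-readable partitioning rule — a conjunction of threshold conditions
#' such as `stroke_mortality < 0.008` — that assigns districts to a
#' cluster. Rules are mutually exclusive and exhaustive, and thresholds are
#' on the raw measurement scale so domain experts can read them directly.
#'
#' @name cluster_profiling
NULL

#' Fit a classification tree of cluster membership
#'
#' Greedy binary recursive partitioning by Gini impurity, with splits at
#' midpoints between adjacent distinct feature values, grown until leaves
#' are pure or the depth/leaf-size limits bind. No pruning, surrogate or
#' competitor splits: the tree is a descriptive device, not a predictive
#' product. Backed by [rpart::rpart()] with `cp = 0`, `maxsurrogate = 0`,
#' `maxcompete = 0`.
#'
#' @param table_raw an [indicator_table()] or matrix of raw-scale
#'   (unstandardized) indicator values.
#' @param labels cluster label per unit.
#' @param max_depth maximum tree depth (default 6).
#' @param min_leaf minimum units per leaf (default 5).
#' @return A `cluster_tree` list wrapping the fitted `rpart` object, the
#'   training data and labels.
#' @export
fit_tree <- function(table_raw, labels, max_depth = 6, min_leaf = 5) {
  X <- as_values_matrix(table_raw)
  labels <- check_partition(X, labels)
  stopifnot(max_depth >= 1, min_leaf >= 1)
  df <- as.data.frame(X)
  names(df) <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  df$.cluster <- factor(labels)
  if (nlevels(df$.cluster) == 1L) {
    tree <- NULL # single class: trivial one-leaf tree
  } else {
    tree <- rpart::rpart(
      .cluster ~ ., data = df, method = "class",
      control = rpart::rpart.control(cp = 0, maxdepth = max_depth,
                                     minbucket = min_leaf,
                                     minsplit = 2 * min_leaf,
                                     maxsurrogate = 0, maxcompete = 0,
                                     xval = 0))
  }
  structure(list(rpart = tree, features = setdiff(names(df), ".cluster"),
                 X = X, labels = labels),
            class = "cluster_tree")
}

#' Predicted cluster for each training unit
#' @param tree a `cluster_tree` from [fit_tree()].
#' @return integer-coded predicted labels (same coding as the input labels).
#' @export
predict_tree <- function(tree) {
  if (is.null(tree$rpart)) return(tree$labels)
  cls <- as.character(stats::predict(tree$rpart, type = "class"))
  type_convert_labels(cls, tree$labels)
}

type_convert_labels <- function(chr, template) {
  if (is.numeric(template)) as.numeric(chr) else chr
}

#' Extract partitioning rules from a fitted cluster tree
#'
#' One rule per leaf: the conjunction of `<` / `>=` threshold conditions on
#' the root-to-leaf path, the leaf's majority cluster, and its coverage
#' (`n_covered` training units reach the leaf, `n_correct` of them belong
#' to the predicted cluster). Applying the rule set to the training data
#' reproduces the tree's predictions exactly.
#'
#' @param tree a `cluster_tree` from [fit_tree()].
#' @return A `rule_set` list: `rules` (each with `conditions`
#'   — data frame `indicator`, `operator`, `threshold` —, `cluster`,
#'   `n_covered`, `n_correct`) and `overall_accuracy`.
#' @export
extract_rules <- function(tree) {
  labels <- tree$labels
  if (is.null(tree$rpart)) {
    rule <- list(conditions = data.frame(indicator = character(0),
                                         operator = character(0),
                                         threshold = numeric(0),
                                         stringsAsFactors = FALSE),
                 cluster = labels[1], n_covered = length(labels),
                 n_correct = length(labels))
    return(structure(list(rules = list(rule), overall_accuracy = 1),
                     class = "rule_set"))
  }
  fr <- tree$rpart$frame
  splits <- tree$rpart$splits
  node_ids <- as.integer(rownames(fr))
  leaf_ids <- node_ids[fr$var == "<leaf>"]
  # map each internal node to its split row: rows of `splits` appear in
  # frame order for primary splits (maxcompete = maxsurrogate = 0)
  internal <- node_ids[fr$var != "<leaf>"]
  split_row <- stats::setNames(seq_along(internal), internal)
  ylevels <- attr(tree$rpart, "ylevels")
  where_node <- node_ids[tree$rpart$where]
  rules <- lapply(leaf_ids, function(leaf) {
    conds <- list()
    node <- leaf
    while (node > 1) {
      parent <- node %/% 2
      srow <- splits[split_row[as.character(parent)], ]
      var <- as.character(fr$var[node_ids == parent])
      thr <- srow["index"]
      # ncat -1: left child is var < threshold; +1: left is var >= threshold
      left_is_lt <- srow["ncat"] == -1
      is_left <- node %% 2 == 0
      op <- if (is_left == left_is_lt) "<" else ">="
      conds[[length(conds) + 1L]] <- data.frame(
        indicator = var, operator = op, threshold = unname(thr),
        stringsAsFactors = FALSE)
      node <- parent
    }
    conds <- if (length(conds)) do.call(rbind, rev(conds)) else
      data.frame(indicator = character(0), operator = character(0),
                 threshold = numeric(0), stringsAsFactors = FALSE)
    in_leaf <- where_node == leaf
    pred <- type_convert_labels(ylevels[fr$yval[node_ids == leaf]], labels)
    list(conditions = conds, cluster = pred,
         n_covered = sum(in_leaf),
         n_correct = sum(labels[in_leaf] == pred))
  })
  acc <- sum(vapply(rules, function(r) r$n_correct, 0)) / length(labels)
  structure(list(rules = rules, overall_accuracy = acc), class = "rule_set")
}

#' Apply a rule set to data
#'
#' @param rules a `rule_set` from [extract_rules()].
#' @param table an [indicator_table()] or matrix on the raw scale.
#' @return predicted cluster per unit.
#' @export
apply_rules <- function(rules, table) {
  X <- as_values_matrix(table)
  n <- nrow(X)
  out <- rep(rules$rules[[1]]$cluster, n)
  assigned <- rep(FALSE, n)
  for (r in rules$rules) {
    sel <- rep(TRUE, n)
    for (j in seq_len(nrow(r$conditions))) {
      v <- X[, r$conditions$indicator[j]]
      thr <- r$conditions$threshold[j]
      sel <- sel & if (r$conditions$operator[j] == "<") v < thr else v >= thr
    }
    out[sel] <- r$cluster
    assigned <- assigned | sel
  }
  if (!all(assigned)) stop("rule set is not exhaustive", call. = FALSE)
  out
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("%d partitioning rule(s), overall accuracy %.3f\n",
              length(x$rules), x$overall_accuracy))
  for (i in seq_along(x$rules)) {
    r <- x$rules[[i]]
    cond <- if (nrow(r$conditions)) {
      paste(sprintf("%s %s %.4g", r$conditions$indicator,
                    r$conditions$operator, r$conditions$threshold),
            collapse = " AND ")
    } else "(always)"
    cat(sprintf("  rule %d: IF %s THEN cluster %s  [%d/%d correct]\n",
                i, cond, r$cluster, r$n_correct, r$n_covered))
  }
  invisible(x)
}

#' Rank indicators by their importance in the cluster tree
#'
#' Importance is the total Gini impurity decrease attributed to each
#' indicator's primary splits, normalized to sum to one; indicators unused
#' by the tree score zero. The top-ranked indicators are the features that
#' best distinguish the clusters.
#'
#' @param tree a `cluster_tree` from [fit_tree()].
#' @return data frame `indicator`, `importance`, sorted decreasing.
#' @export
rank_features <- function(tree) {
  imp <- stats::setNames(rep(0, length(tree$features)), tree$features)
  if (!is.null(tree$rpart)) {
    vi <- tree$rpart$variable.importance
    if (!is.null(vi)) imp[names(vi)] <- vi
    if (sum(imp) > 0) imp <- imp / sum(imp)
  }
  out <- data.frame(indicator = names(imp), importance = unname(imp),
                    stringsAsFactors = FALSE)
  out[order(-out$importance, out$indicator), , drop = FALSE]
}
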