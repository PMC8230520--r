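#' Rank features by random-forest Gini importance
#'
#' With many more features than subjects, classifiers degrade unless the
#' feature space is cut down. A random forest is grown on the training rows
#' and each feature is scored by the mean decrease in Gini impurity it
#' contributes across trees; scores are normalized to sum to 1 and sorted
#' in descending order (ties broken by feature name). Unlike PCA, this
#' keeps the original, interpretable features.
#'
#' @param features A feature table (metadata columns plus numeric
#'   features), typically scaled with [standard_scale()].
#' @param label Name of the class-label column.
#' @param n_trees Number of trees.
#' @param seed Integer seed (the ranking is deterministic under it).
#' @return A tibble of class `feature_ranking` with columns `feature`,
#'   `importance` (descending).
#' @export
gini_rank <- function(features, label = "label", n_trees = 300, seed = 1L) {
  y <- droplevels(factor(features[[label]]))
  if (nlevels(y) < 2) {
    abort("Need at least 2 classes to rank features",
          class = "frailmotion_validation_error")
  }
  fcols <- feature_columns(features)
  X <- as.matrix(features[fcols])
  if (!all(is.finite(X))) {
    abort("Feature matrix contains non-finite values",
          class = "frailmotion_validation_error")
  }
  rf <- ranger::ranger(
    x = X, y = y, num.trees = n_trees, importance = "impurity",
    seed = seed, num.threads = 1
  )
  imp <- pmax(rf$variable.importance, 0)
  total <- sum(imp)
  imp <- if (total > 0) imp / total else rep(1 / length(imp), length(imp))
  ord <- order(-imp, names(imp))
  tibble::new_tibble(
    tibble::tibble(feature = names(imp)[ord], importance = unname(imp[ord])),
    class = "feature_ranking"
  )
}

#' Keep the top-ranked features
#'
#' @param features A feature table.
#' @param ranking A `feature_ranking` from [gini_rank()].
#' @param ns Number of features to keep (1 <= ns <= feature count).
#' @return The feature table with metadata columns followed by the first
#'   `ns` features of the ranking, in ranking order.
#' @export
select_top <- function(features, ranking, ns) {
  fcols <- feature_columns(features)
  if (ns < 1 || ns > length(fcols)) {
    abort(sprintf("`ns` must be in 1..%d", length(fcols)),
          class = "frailmotion_validation_error")
  }
  keep <- ranking$feature[seq_len(ns)]
  missing_f <- setdiff(keep, fcols)
  if (length(missing_f) > 0) {
    abort("Ranking refers to features absent from the table",
          class = "frailmotion_validation_error")
  }
  meta <- setdiff(names(features), fcols)
  out <- features[c(meta, keep)]
  attr(out, "scaling") <- attr(features, "scaling")
  out
}
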