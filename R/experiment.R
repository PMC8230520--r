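#' Run a repeated holdout-classification experiment
#'
#' The experiment mirrors the full methodology end to end, once per
#' repeat and per design cell (exercise set x family set x subject count):
#' balance the labels, subsample `n_subjects`, split into training and
#' holdout subjects, aggregate histogram features with ranges fitted on the
#' training rows, standard-scale with training-fitted parameters, rank
#' features by Gini importance on the training rows, keep the top `ns`,
#' tune each requested classifier by randomized-search CV, and score it on
#' the held-out subjects. Nothing downstream of the split ever sees a
#' holdout row, so the reported accuracies are subject-disjoint
#' generalization estimates.
#'
#' @param track_set A `track_set` from [extract_track_sets()].
#' @param subjects Subject table with `subject_id` and the label column.
#' @param label `"frailty_class"` or `"gender"`.
#' @param classifiers Classifier kinds to evaluate (see
#'   [tune_classifier()]).
#' @param exercise_sets List of character vectors of exercises per design
#'   cell; default one cell with every exercise in the track set.
#' @param family_sets List of family subsets per design cell; default one
#'   cell with all extracted families.
#' @param n_subjects Integer vector of cohort sizes to evaluate; default
#'   the full balanced size.
#' @param ns Number of top-ranked features kept (capped at the available
#'   feature count). About 150 is a good default: fewer features starve
#'   the classifiers, many more re-introduce the dimensionality curse.
#' @param nb,aggregation Aggregation settings (see
#'   [build_feature_table()]).
#' @param k,n_iter Tuning settings (see [tune_classifier()]).
#' @param holdout_frac Fraction of subjects held out (stratified).
#' @param repeats Independent repeats (new balancing, subsample and split
#'   each time).
#' @param seed Master seed; the entire experiment is reproducible under
#'   it.
#' @return An `experiment_report` tibble: one row per repeat x cell x
#'   classifier with the holdout `accuracy` (percent). Supports
#'   [glance()] (median/quartiles per cell) and [autoplot()].
#' @export
run_experiment <- function(track_set, subjects, label = "frailty_class",
                           classifiers = classifier_kinds(),
                           exercise_sets = NULL, family_sets = NULL,
                           n_subjects = NULL, ns = 150,
                           nb = 20, aggregation = default_aggregation(),
                           k = 5L, n_iter = 50L, holdout_frac = 0.25,
                           repeats = 10L, seed = 1L) {
  classifiers <- match.arg(classifiers, classifier_kinds(),
                           several.ok = TRUE)
  if (inherits(track_set, "track_set")) {
    exercise_sets <- exercise_sets %||% list(unique(track_set$exercise))
    family_sets <- family_sets %||% list(attr(track_set, "families"))
  } else {
    parsed <- parse_feature_names(feature_columns(track_set))
    exercise_sets <- exercise_sets %||%
      list(unique(parsed$exercise[!is.na(parsed$exercise)]))
    family_sets <- family_sets %||% list(unique(parsed$family))
  }
  subjects <- tibble::as_tibble(subjects)
  if (!label %in% names(subjects)) {
    abort(paste0("No label column `", label, "` in subjects"),
          class = "frailmotion_configuration_error")
  }

  from_tracks <- inherits(track_set, "track_set")
  rows <- list()
  withr::with_seed(seed, {
    for (r in seq_len(repeats)) {
      bal_seed <- sample.int(2^31 - 2, 1)
      for (exs in exercise_sets) {
        for (fams in family_sets) {
          cell <- if (from_tracks) {
            prepare_cell(track_set, subjects, label, exs, fams,
                         aggregation, nb, bal_seed)
          } else {
            prepare_cell_features(track_set, subjects, label, exs, fams,
                                  bal_seed)
          }
          sizes <- n_subjects %||% nrow(cell$subjects)
          for (n_sub in sizes) {
            if (n_sub > nrow(cell$subjects)) {
              abort(sprintf(
                "n_subjects = %d exceeds the %d available balanced subjects",
                n_sub, nrow(cell$subjects)),
                class = "frailmotion_configuration_error")
            }
            res <- if (from_tracks) {
              run_cell(cell, n_sub, classifiers, ns, nb, aggregation,
                       k, n_iter, holdout_frac)
            } else {
              run_cell_features(cell, n_sub, classifiers, ns,
                                k, n_iter, holdout_frac)
            }
            res$repeat_ <- r
            res$exercise_set <- paste(exs, collapse = "+")
            res$family_set <- paste(fams, collapse = "+")
            res$n_subjects <- n_sub
            rows[[length(rows) + 1]] <- res
          }
        }
      }
    }
  })
  out <- dplyr::bind_rows(rows)
  out <- out[, c("classifier", "exercise_set", "family_set", "n_subjects",
                 "repeat_", "accuracy", "cv_accuracy")]
  tibble::new_tibble(out, class = "experiment_report",
                     label = label, ns = ns, nb = nb, k = k,
                     n_iter = n_iter, holdout_frac = holdout_frac,
                     seed = seed)
}

# Balance labels and restrict the track set to one design cell.
prepare_cell <- function(track_set, subjects, label, exercises, families,
                         aggregation, nb, bal_seed) {
  ts <- track_set[track_set$exercise %in% exercises, ]
  per_ex <- table(ts$subject_id)
  complete <- names(per_ex)[per_ex == length(exercises)]
  subj <- subjects[subjects$subject_id %in% complete, ]
  balanced <- balance_labels(subj, label, seed = bal_seed)
  list(track_set = ts, subjects = balanced, label = label,
       exercises = exercises, families = families)
}

run_cell <- function(cell, n_sub, classifiers, ns, nb, aggregation,
                     k, n_iter, holdout_frac) {
  lab <- factor(cell$subjects[[cell$label]])
  pick <- unlist(lapply(levels(droplevels(lab)), function(cl) {
    idx <- which(lab == cl)
    sample(idx, round(n_sub / nlevels(droplevels(lab))))
  }))
  subj <- cell$subjects[pick, ]
  y <- droplevels(factor(subj[[cell$label]]))

  test <- unlist(lapply(levels(y), function(cl) {
    idx <- which(y == cl)
    sample(idx, max(1L, round(holdout_frac * length(idx))))
  }))
  is_train <- !seq_len(nrow(subj)) %in% test
  train_ids <- subj$subject_id[is_train]

  ts <- cell$track_set[cell$track_set$subject_id %in% subj$subject_id, ]
  feats <- build_feature_table(filter_track_families(ts, cell$families),
                               exercises = cell$exercises,
                               aggregation = aggregation, nb = nb,
                               fit_subjects = train_ids)
  feats <- dplyr::left_join(
    feats, subj[, c("subject_id", cell$label)], by = "subject_id")
  names(feats)[names(feats) == cell$label] <- "label"
  fit_rows <- which(feats$subject_id %in% train_ids)
  feats <- standard_scale(feats, fit_rows = fit_rows)

  train <- feats[fit_rows, ]
  hold <- feats[-fit_rows, ]
  rank_seed <- sample.int(2^31 - 2, 1)
  ranking <- gini_rank(train, seed = rank_seed)
  ns_used <- min(ns, nrow(ranking))
  train_s <- select_top(train, ranking, ns_used)
  hold_s <- select_top(hold, ranking, ns_used)

  dplyr::bind_rows(lapply(classifiers, function(kind) {
    tune_seed <- sample.int(2^31 - 2, 1)
    m <- tune_classifier(train_s, kind, k = k, n_iter = n_iter,
                         seed = tune_seed)
    tibble::tibble(classifier = kind,
                   accuracy = evaluate_holdout(m, hold_s),
                   cv_accuracy = m$cv_accuracy)
  }))
}

# Feature-table path: used when the features were already aggregated (e.g.
# the CSV written by cmd_extract()). Histogram ranges are then frozen from
# extraction time; scaling, ranking and tuning remain training-only.
parse_feature_names <- function(nms) {
  has_prefix <- grepl("\\|", nms)
  exercise <- ifelse(has_prefix, sub("\\|.*$", "", nms), NA_character_)
  rest <- ifelse(has_prefix, sub("^[^|]*\\|", "", nms), nms)
  tibble::tibble(name = nms, exercise = exercise,
                 family = sub(":.*$", "", rest))
}

prepare_cell_features <- function(features, subjects, label, exercises,
                                  families, bal_seed) {
  parsed <- parse_feature_names(feature_columns(features))
  keep <- parsed$family %in% families &
    (is.na(parsed$exercise) | parsed$exercise %in% exercises)
  cols <- parsed$name[keep]
  if (length(cols) == 0) {
    abort("No features match the requested exercise/family sets",
          class = "frailmotion_configuration_error")
  }
  feats <- features[c("subject_id", cols)]
  subj <- subjects[subjects$subject_id %in% feats$subject_id, ]
  balanced <- balance_labels(subj, label, seed = bal_seed)
  list(features = feats, subjects = balanced, label = label)
}

run_cell_features <- function(cell, n_sub, classifiers, ns,
                              k, n_iter, holdout_frac) {
  lab <- droplevels(factor(cell$subjects[[cell$label]]))
  pick <- unlist(lapply(levels(lab), function(cl) {
    idx <- which(lab == cl)
    sample(idx, round(n_sub / nlevels(lab)))
  }))
  subj <- cell$subjects[pick, ]
  y <- droplevels(factor(subj[[cell$label]]))
  test <- unlist(lapply(levels(y), function(cl) {
    idx <- which(y == cl)
    sample(idx, max(1L, round(holdout_frac * length(idx))))
  }))
  is_train <- !seq_len(nrow(subj)) %in% test
  train_ids <- subj$subject_id[is_train]

  feats <- cell$features[match(subj$subject_id, cell$features$subject_id), ]
  feats$label <- y
  fit_rows <- which(feats$subject_id %in% train_ids)
  feats <- standard_scale(feats, fit_rows = fit_rows)
  train <- feats[fit_rows, ]
  hold <- feats[-fit_rows, ]
  ranking <- gini_rank(train, seed = sample.int(2^31 - 2, 1))
  ns_used <- min(ns, nrow(ranking))
  train_s <- select_top(train, ranking, ns_used)
  hold_s <- select_top(hold, ranking, ns_used)
  dplyr::bind_rows(lapply(classifiers, function(kind) {
    m <- tune_classifier(train_s, kind, k = k, n_iter = n_iter,
                         seed = sample.int(2^31 - 2, 1))
    tibble::tibble(classifier = kind,
                   accuracy = evaluate_holdout(m, hold_s),
                   cv_accuracy = m$cv_accuracy)
  }))
}

# Restrict every feature_tracks object to a family subset.
filter_track_families <- function(track_set, families) {
  out <- track_set
  out$tracks <- lapply(out$tracks, function(tr) {
    keep <- tr$family %in% families
    tr$matrix <- tr$matrix[, keep, drop = FALSE]
    tr$family <- tr$family[keep]
    tr
  })
  out
}

#' Summarise an experiment report per design cell
#'
#' @param x An `experiment_report`.
#' @param ... Ignored.
#' @return A tibble with median and quartile holdout accuracy per
#'   classifier and design cell.
#' @export
glance.experiment_report <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), classifier, .data$exercise_set,
                    .data$family_set, .data$n_subjects),
    median_accuracy = median(accuracy),
    q1 = quantile(accuracy, 0.25),
    q3 = quantile(accuracy, 0.75),
    n_repeats = dplyr::n(),
    .groups = "drop"
  )
}

#' Box plots of classifier accuracy across design cells
#'
#' @param object An `experiment_report`.
#' @param facet `"exercise_set"`, `"family_set"` or `"n_subjects"`; the
#'   design axis on the x axis.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.experiment_report <- function(object,
                                       facet = c("exercise_set",
                                                 "family_set",
                                                 "n_subjects"), ...) {
  facet <- match.arg(facet)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data[[facet]]), y = accuracy,
                               fill = classifier)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(0.8)) +
    ggplot2::labs(x = facet, y = "holdout accuracy [%]") +
    ggplot2::theme_minimal()
}

#' @export
generics::tidy

#' @export
generics::glance
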