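#' Tune a classifier by randomized search with stratified k-fold CV
#'
#' Draws `n_iter` hyper-parameter combinations at random from the
#' documented search space of the classifier kind, scores each by the mean
#' accuracy over `k` stratified cross-validation folds of the training
#' rows, picks the best (ties resolved by draw order) and refits it on all
#' training rows. Random search covers a wide space at a fraction of the
#' cost of a grid.
#'
#' Search spaces: KNN `k` 1-30, uniform or distance weights; SVC rbf or
#' linear kernel, cost 1e-2..1e3 and kernel width 1e-4..1e1 (log-uniform);
#' MLP one hidden layer of 4-16 units, L2 decay 1e-5..1e-1 (log-uniform);
#' bagged trees 10-200 trees, bootstrap fraction 0.5-1. The voting
#' classifier tunes the four base kinds on shared folds and averages their
#' predicted class probabilities (soft voting).
#'
#' @param features Training feature table (rows = subjects); must contain
#'   the label column.
#' @param kind One of `"knn"`, `"svc"`, `"mlp"`, `"bag"`, `"vote"`.
#' @param label Name of the class-label column.
#' @param k Number of CV folds, between 5 and 10.
#' @param n_iter Number of random hyper-parameter draws.
#' @param seed Integer seed; the whole tuning run is reproducible under it.
#' @return A `frailty_model`: list with the refitted model, `best_params`,
#'   `cv_accuracy` (percent), the search `history`, and the tuning
#'   settings. Supports [predict()], [tidy()] and [glance()].
#' @export
tune_classifier <- function(features, kind, label = "label",
                            k = 5L, n_iter = 50L, seed = 1L) {
  kind <- match.arg(kind, classifier_kinds())
  if (k < 5 || k > 10) {
    abort("`k` must be between 5 and 10", class = "frailmotion_validation_error")
  }
  y <- droplevels(factor(features[[label]]))
  if (nlevels(y) < 2) {
    abort("Training labels contain a single class",
          class = "frailmotion_validation_error")
  }
  X <- as.matrix(features[feature_columns(features)])

  withr::with_seed(seed, {
    folds <- stratified_folds(y, k)
    if (kind == "vote") {
      base <- lapply(c("knn", "svc", "mlp", "bag"), function(kk) {
        tune_kind(X, y, kk, folds, n_iter)
      })
      names(base) <- c("knn", "svc", "mlp", "bag")
      cv <- vote_cv_accuracy(X, y, folds, lapply(base, `[[`, "best_params"))
      fit <- structure(
        list(kind = "vote",
             fit = lapply(base, function(b) fit_classifier(
               b$kind, X, y, b$best_params)),
             params = lapply(base, `[[`, "best_params"),
             levels = levels(y)),
        class = "base_classifier")
      res <- list(best_params = lapply(base, `[[`, "best_params"),
                  cv_accuracy = cv,
                  history = dplyr::bind_rows(lapply(base, `[[`, "history"),
                                             .id = "base_kind"))
    } else {
      res <- tune_kind(X, y, kind, folds, n_iter)
      fit <- fit_classifier(kind, X, y, res$best_params)
      res$history$base_kind <- kind
    }
  })

  structure(list(kind = kind, model = fit,
                 best_params = res$best_params,
                 cv_accuracy = res$cv_accuracy,
                 history = res$history,
                 k = as.integer(k), n_iter = as.integer(n_iter),
                 seed = as.integer(seed),
                 features = colnames(X), levels = levels(y)),
            class = "frailty_model")
}

# Stratified fold assignment; every fold must see both classes in training.
stratified_folds <- function(y, k) {
  if (min(table(y)) < k) {
    abort("Too few subjects per class for stratified folds",
          class = "frailmotion_stratification_error")
  }
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

tune_kind <- function(X, y, kind, folds, n_iter) {
  k <- max(folds)
  draws <- lapply(seq_len(n_iter), function(i)
    draw_params(kind, ncol(X), nrow(X)))
  accs <- vapply(draws, function(par) {
    fold_acc <- vapply(seq_len(k), function(f) {
      tr <- folds != f
      m <- fit_classifier(kind, X[tr, , drop = FALSE], y[tr], par)
      mean(predict_class(m, X[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1))
    mean(fold_acc) * 100
  }, numeric(1))
  best <- which.max(accs)   # ties -> first drawn
  list(kind = kind, best_params = draws[[best]],
       cv_accuracy = accs[best],
       history = tibble::tibble(iter = seq_len(n_iter),
                                params = draws, cv_accuracy = accs))
}

vote_cv_accuracy <- function(X, y, folds, best_params) {
  k <- max(folds)
  fold_acc <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    probs <- lapply(names(best_params), function(kk) {
      m <- fit_classifier(kk, X[tr, , drop = FALSE], y[tr], best_params[[kk]])
      predict_prob(m, X[!tr, , drop = FALSE])
    })
    p <- Reduce(`+`, probs) / length(probs)
    pred <- levels(y)[max.col(p, ties.method = "first")]
    mean(pred == as.character(y[!tr]))
  }, numeric(1))
  mean(fold_acc) * 100
}

#' @export
print.frailty_model <- function(x, ...) {
  cat(sprintf("<frailty_model> %s: CV accuracy %.1f%% (k=%d, n_iter=%d)\n",
              x$kind, x$cv_accuracy, x$k, x$n_iter))
  invisible(x)
}

#' Predict classes or probabilities for new subjects
#'
#' @param object A `frailty_model`.
#' @param newdata A feature table containing the model's feature columns
#'   (extra columns ignored), or a numeric matrix.
#' @param type `"class"` or `"prob"`.
#' @param ... Ignored.
#' @return A factor of predicted classes, or an n-by-classes probability
#'   matrix.
#' @export
predict.frailty_model <- function(object, newdata, type = c("class", "prob"),
                                  ...) {
  type <- match.arg(type)
  X <- if (is.matrix(newdata)) newdata else {
    missing_f <- setdiff(object$features, names(newdata))
    if (length(missing_f) > 0) {
      abort(paste0("newdata lacks model feature(s), e.g. ", missing_f[1]),
            class = "frailmotion_validation_error")
    }
    as.matrix(newdata[object$features])
  }
  if (type == "class") predict_class(object$model, X)
  else {
    p <- predict_prob(object$model, X)
    colnames(p) <- object$levels
    p
  }
}

#' Holdout accuracy of a tuned model
#'
#' Percent of correct predictions on subjects never seen during scaling,
#' ranking or tuning.
#'
#' @param model A `frailty_model`.
#' @param features Holdout feature table including the label column.
#' @param label Name of the class-label column.
#' @return Accuracy in percent (0-100).
#' @export
evaluate_holdout <- function(model, features, label = "label") {
  if (nrow(features) == 0) {
    abort("Empty holdout set", class = "frailmotion_validation_error")
  }
  truth <- as.character(features[[label]])
  pred <- as.character(predict(model, features, type = "class"))
  100 * mean(pred == truth)
}

#' Broom-style accessors for tuned models
#'
#' `tidy()` returns the randomized-search history (one row per draw);
#' `glance()` a one-row summary.
#'
#' @param x A `frailty_model`.
#' @param ... Ignored.
#' @return A tibble.
#' @importFrom generics tidy glance
#' @export
tidy.frailty_model <- function(x, ...) {
  h <- x$history
  h$kind <- x$kind
  h
}

#' @rdname tidy.frailty_model
#' @export
glance.frailty_model <- function(x, ...) {
  tibble::tibble(kind = x$kind, cv_accuracy = x$cv_accuracy,
                 k = x$k, n_iter = x$n_iter, seed = x$seed,
                 n_features = length(x$features))
}
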