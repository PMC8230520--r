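# The five classifier kinds and their randomized-search spaces.
#
# KNN: majority (optionally distance-weighted) vote among the k nearest
#   training subjects. Implemented here directly because soft voting needs
#   class probabilities and the search space includes distance weighting.
# SVC: kernel support vector classifier (e1071), rbf or linear.
# MLP: single-hidden-layer perceptron (nnet) with L2 weight decay.
# BAG: bagging of decision trees = random forest with mtry = p and
#   bootstrap subsample fraction as a hyper-parameter.
# VOTE: soft voting — the mean of the predicted class probabilities of the
#   four tuned base models.

#' The five available classifier kinds
#' @return `c("knn", "svc", "mlp", "bag", "vote")`.
#' @export
classifier_kinds <- function() c("knn", "svc", "mlp", "bag", "vote")

# One random hyper-parameter draw per call; assumes an active RNG stream.
draw_params <- function(kind, n_features, n_train) {
  switch(kind,
    knn = list(k = sample(1:min(30, n_train - 1), 1),
               weights = sample(c("uniform", "distance"), 1)),
    svc = list(kernel = sample(c("radial", "linear"), 1),
               cost = 10^runif(1, -2, 3),
               gamma = 10^runif(1, -4, 1)),
    mlp = list(size = sample(4:16, 1),
               decay = 10^runif(1, -5, -1),
               maxit = 100L),
    bag = list(ntree = sample(10:200, 1),
               sample_frac = runif(1, 0.5, 1)),
    abort(paste0("No search space for kind: ", kind),
          class = "frailmotion_validation_error")
  )
}

fit_classifier <- function(kind, X, y, params) {
  y <- droplevels(factor(y))
  fit <- switch(kind,
    knn = list(X = X, y = y, k = params$k, weights = params$weights),
    svc = e1071::svm(x = X, y = y, kernel = params$kernel,
                     cost = params$cost, gamma = params$gamma,
                     probability = TRUE, scale = FALSE),
    mlp = nnet::nnet(x = X, y = nnet::class.ind(y), size = params$size,
                     decay = params$decay, maxit = params$maxit,
                     softmax = TRUE, MaxNWts = 1e6, trace = FALSE),
    bag = randomForest::randomForest(
      x = X, y = y, ntree = params$ntree, mtry = ncol(X),
      sampsize = max(2L, ceiling(params$sample_frac * nrow(X))),
      replace = TRUE),
    abort(paste0("Unknown classifier kind: ", kind),
          class = "frailmotion_validation_error")
  )
  structure(list(kind = kind, params = params, fit = fit,
                 levels = levels(y)),
            class = "base_classifier")
}

# n x n_levels matrix of class probabilities, columns in level order.
predict_prob <- function(model, X) {
  lev <- model$levels
  p <- switch(model$kind,
    knn = knn_prob(model$fit, X),
    svc = {
      pr <- attr(predict(model$fit, X, probability = TRUE), "probabilities")
      pr[, lev, drop = FALSE]
    },
    mlp = {
      pr <- predict(model$fit, X)
      pr[, lev, drop = FALSE]
    },
    bag = predict(model$fit, X, type = "prob")[, lev, drop = FALSE],
    vote = {
      ps <- lapply(model$fit, function(b) predict_prob(b, X))
      Reduce(`+`, ps) / length(ps)
    }
  )
  unname(as.matrix(p))
}

predict_class <- function(model, X) {
  p <- predict_prob(model, X)
  factor(model$levels[max.col(p, ties.method = "first")],
         levels = model$levels)
}

knn_prob <- function(fit, X) {
  X <- as.matrix(X)
  tr <- fit$X
  # squared distances via the expansion ||a-b||^2 = ||a||^2+||b||^2-2ab
  d2 <- outer(rowSums(X^2), rowSums(tr^2), "+") - 2 * X %*% t(tr)
  d2[d2 < 0] <- 0
  lev <- levels(fit$y)
  out <- matrix(0, nrow(X), length(lev))
  for (i in seq_len(nrow(X))) {
    nn <- order(d2[i, ])[seq_len(fit$k)]
    w <- if (fit$weights == "distance") {
      1 / (sqrt(d2[i, nn]) + 1e-9)
    } else rep(1, length(nn))
    votes <- tapply(w, fit$y[nn], sum, default = 0)
    out[i, ] <- votes[lev] / sum(w)
  }
  colnames(out) <- lev
  out
}
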