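make_feature_tbl <- function(X, y) {
  f <- tibble::as_tibble(as.data.frame(X))
  names(f) <- paste0("ED:f", sprintf("%03d", seq_len(ncol(X))), ":b01")
  f$label <- y
  f$subject_id <- sprintf("S%03d", seq_len(nrow(X)))
  f
}

test_that("Gini ranking recovers a planted signal feature", {
  for (s in 1:5) {
    withr::with_seed(2000 + s, {
      n <- 100
      y <- factor(rep(c("a", "b"), n / 2))
      X <- matrix(rnorm(n * 100), n, 100)
      X[, 37] <- ifelse(y == "a", 1, -1) + rnorm(n, 0, 0.3)
      f <- make_feature_tbl(X, y)
      rk <- gini_rank(f, n_trees = 200, seed = s)
      expect_equal(rk$feature[1], "ED:f037:b01")
      expect_equal(sum(rk$importance), 1, tolerance = 1e-9)
      expect_true(all(rk$importance >= 0))
      expect_true(all(diff(rk$importance) <= 1e-12))
    })
  }
})

test_that("ranking is column-permutation equivariant and flat on pure
           noise", {
  withr::with_seed(42, {
    n <- 80
    y <- factor(rep(c("a", "b"), n / 2))
    X <- matrix(rnorm(n * 30), n, 30)
    X[, 5] <- as.numeric(y) + rnorm(n, 0, 0.2)
    f1 <- make_feature_tbl(X, y)
    perm <- sample(30)
    f2 <- make_feature_tbl(X[, perm], y)
    # rename so column j of f2 carries the original feature's name
    names(f2)[1:30] <- names(f1)[perm]
    r1 <- gini_rank(f1, n_trees = 300, seed = 9)
    r2 <- gini_rank(f2, n_trees = 300, seed = 9)
    expect_identical(r1$feature[1], r2$feature[1])
    expect_equal(r1$importance[1], r2$importance[1], tolerance = 0.02)

    # all-noise design: no feature dominates
    Xn <- matrix(rnorm(n * 200), n, 200)
    rn <- gini_rank(make_feature_tbl(Xn, y), n_trees = 300, seed = 5)
    expect_lt(max(rn$importance), 5 * median(rn$importance))
  })
  expect_error(gini_rank(make_feature_tbl(matrix(rnorm(40), 10, 4),
                                          factor(rep("a", 10)))),
               class = "frailmotion_validation_error")
})

test_that("select_top keeps the first ns ranked features in order", {
  withr::with_seed(1, {
    f <- make_feature_tbl(matrix(rnorm(40 * 10), 40, 10),
                          factor(rep(c("a", "b"), 20)))
    rk <- gini_rank(f, n_trees = 50, seed = 2)
    all_cols <- select_top(f, rk, 10)
    expect_setequal(setdiff(names(all_cols), c("label", "subject_id")),
                    rk$feature)
    one <- select_top(f, rk, 1)
    expect_identical(setdiff(names(one), c("label", "subject_id")),
                     rk$feature[1])
    top3 <- select_top(f, rk, 3)
    expect_identical(setdiff(names(top3), c("label", "subject_id")),
                     rk$feature[1:3])
    expect_error(select_top(f, rk, 11),
                 class = "frailmotion_validation_error")
    expect_error(select_top(f, rk, 0),
                 class = "frailmotion_validation_error")
  })
})

test_that("every classifier kind separates clean blobs and is
           seed-reproducible", {
  withr::with_seed(7, {
    n <- 60
    y <- factor(rep(c("a", "b"), n / 2))
    X <- matrix(rnorm(n * 2, sd = 0.4), n, 2) +
      ifelse(y == "a", -1.5, 1.5)
    f <- make_feature_tbl(X, y)
  })
  for (kind in c("knn", "svc", "mlp", "bag", "vote")) {
    m <- tune_classifier(f, kind, k = 5, n_iter = 4, seed = 31)
    expect_gte(m$cv_accuracy, 95)
    m2 <- tune_classifier(f, kind, k = 5, n_iter = 4, seed = 31)
    expect_identical(m$cv_accuracy, m2$cv_accuracy)
    expect_identical(m$best_params, m2$best_params)
    # tidy/glance accessors
    expect_s3_class(tidy(m), "tbl_df")
    expect_equal(glance(m)$cv_accuracy, m$cv_accuracy)
  }
})

test_that("shuffled labels give chance-level cross-validated accuracy", {
  accs <- c()
  for (s in 1:3) {
    withr::with_seed(300 + s, {
      n <- 100
      X <- matrix(rnorm(n * 20), n, 20)
      y <- factor(sample(rep(c("a", "b"), n / 2)))
      f <- make_feature_tbl(X, y)
    })
    for (kind in c("knn", "svc")) {
      m <- tune_classifier(f, kind, k = 5, n_iter = 3, seed = s)
      accs <- c(accs, m$cv_accuracy)
    }
  }
  expect_lt(abs(mean(accs) - 50), 10)
})

test_that("holdout evaluation scores exact percent accuracy", {
  withr::with_seed(17, {
    n <- 40
    y <- factor(rep(c("a", "b"), n / 2))
    X <- matrix(rnorm(n * 2, sd = 0.2), n, 2) + ifelse(y == "a", -2, 2)
    f <- make_feature_tbl(X, y)
  })
  m <- tune_classifier(f, "knn", k = 5, n_iter = 3, seed = 1)
  expect_equal(evaluate_holdout(m, f), 100)
  flipped <- f
  flipped$label <- factor(ifelse(f$label == "a", "b", "a"))
  expect_equal(evaluate_holdout(m, flipped), 0)
  expect_error(evaluate_holdout(m, f[0, ]),
               class = "frailmotion_validation_error")
  expect_error(tune_classifier(f, "svc", k = 4),
               class = "frailmotion_validation_error")
  single <- f; single$label <- factor(rep("a", n))
  expect_error(tune_classifier(single, "svc"),
               class = "frailmotion_validation_error")
  tiny <- f[c(1:4, 21:24), ]
  expect_error(tune_classifier(tiny, "knn", k = 5),
               class = "frailmotion_stratification_error")
})

test_that("the experiment runner is reproducible and leak-free by
           construction", {
  coh <- quick_sts_cohort(n_per_class = 8, seed = 55)
  ts <- extract_track_sets(coh$recordings)
  r1 <- run_experiment(ts, coh$subjects, classifiers = "knn",
                       ns = 30, nb = 5, n_iter = 2, repeats = 2, seed = 99)
  r2 <- run_experiment(ts, coh$subjects, classifiers = "knn",
                       ns = 30, nb = 5, n_iter = 2, repeats = 2, seed = 99)
  expect_identical(tibble::as_tibble(r1), tibble::as_tibble(r2))
  expect_equal(nrow(r1), 2)
  expect_true(all(r1$accuracy >= 0 & r1$accuracy <= 100))
  expect_error(run_experiment(ts, coh$subjects, classifiers = "knn",
                              n_subjects = 1000, repeats = 1),
               class = "frailmotion_configuration_error")
  g <- glance(r1)
  expect_true(all(c("median_accuracy", "q1", "q3") %in% names(g)))
})
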