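test_that("geometric primitives match their closed forms", {
  a <- spherical_angles(c(0, 0, 0), c(1, 0, 0))
  expect_equal(a$phi, 0); expect_equal(a$theta, pi / 2)
  a <- spherical_angles(c(0, 0, 0), c(0, 1, 0))   # vertical: atan2(0,0) = 0
  expect_equal(a$phi, 0); expect_equal(a$theta, 0)
  a <- spherical_angles(c(0, 0, 0), c(1, 1, sqrt(2)))  # lr = 2
  expect_equal(a$theta, pi / 3)
  expect_equal(a$phi, atan2(sqrt(2), 1))
  expect_error(spherical_angles(c(1, 2, 3), c(1, 2, 3)),
               class = "frailmotion_degenerate_geometry_error")

  expect_equal(euclidean_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(euclidean_distance(c(1, 1, 1), c(1, 1, 1)), 0)

  expect_equal(cosine_dissimilarity(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), 1)
  expect_equal(cosine_dissimilarity(c(0, 0, 0), c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cosine_dissimilarity(c(0, 0, 0), c(1, 2, 3), -c(1, 2, 3)), 2)
  expect_error(cosine_dissimilarity(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               class = "frailmotion_degenerate_geometry_error")

  expect_equal(triangular_area(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), 0.5)
  expect_equal(triangular_area(c(0, 0, 0), c(2, 0, 0), c(0, 3, 0)), 3)
  expect_equal(triangular_area(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)), 0)
})

test_that("geometric primitives agree with brute-force oracles on random
           triples and respect their ranges", {
  withr::with_seed(101, {
    for (i in 1:200) {
      ref <- random_point(); p1 <- random_point(); p2 <- random_point()
      expect_equal(euclidean_distance(p1, p2), bf_distance(p1, p2),
                   tolerance = 1e-12)
      expect_equal(cosine_dissimilarity(ref, p1, p2),
                   bf_cosine_dissimilarity(ref, p1, p2), tolerance = 1e-12)
      expect_equal(triangular_area(ref, p1, p2),
                   bf_triangle_area(ref, p1, p2), tolerance = 1e-7)
      sa <- spherical_angles(p1, p2)
      bf <- bf_spherical(p1, p2)
      expect_equal(unname(c(sa$phi, sa$theta)), unname(bf),
                   tolerance = 1e-12)
      expect_true(sa$theta >= 0 && sa$theta <= pi)
      expect_true(sa$phi > -pi && sa$phi <= pi)
    }
  })
})

test_that("features transform correctly under rigid motions and scaling", {
  withr::with_seed(7, {
    for (i in 1:20) {
      ref <- random_point(); p1 <- random_point(); p2 <- random_point()
      R <- random_rotation(); tr <- runif(3, -5, 5); s <- runif(1, 0.5, 3)
      rigid <- function(p) as.vector(R %*% p + tr)
      # translation+rotation: ED, JCD, JTA invariant; theta/phi change with
      # rotation but are invariant under pure translation
      expect_equal(euclidean_distance(rigid(p1), rigid(p2)),
                   euclidean_distance(p1, p2), tolerance = 1e-9)
      expect_equal(cosine_dissimilarity(rigid(ref), rigid(p1), rigid(p2)),
                   cosine_dissimilarity(ref, p1, p2), tolerance = 1e-9)
      expect_equal(triangular_area(rigid(ref), rigid(p1), rigid(p2)),
                   triangular_area(ref, p1, p2), tolerance = 1e-9)
      expect_equal(spherical_angles(p1 + tr, p2 + tr),
                   spherical_angles(p1, p2), tolerance = 1e-9)
      # uniform scaling: ED ~ s, JTA ~ s^2, SA and JCD invariant
      expect_equal(euclidean_distance(s * p1, s * p2),
                   s * euclidean_distance(p1, p2), tolerance = 1e-9)
      expect_equal(triangular_area(s * ref, s * p1, s * p2),
                   s^2 * triangular_area(ref, p1, p2), tolerance = 1e-9)
      expect_equal(cosine_dissimilarity(s * ref, s * p1, s * p2),
                   cosine_dissimilarity(ref, p1, p2), tolerance = 1e-9)
      expect_equal(spherical_angles(s * p1, s * p2),
                   spherical_angles(p1, p2), tolerance = 1e-9)
    }
  })
})

test_that("track extraction yields the documented per-family counts", {
  g <- generate_recording("sit_to_stand", seed = 31)
  sm <- smooth_recording(g$recording)
  seg <- isolate_cycles(cycle_metric(sm, smooth = FALSE))
  counts <- c(SA = 16L, ED = 210L, JCD = 190L, JTA = 190L)
  for (fam in names(counts)) {
    tr <- extract_tracks(sm, seg, families = fam)
    expect_equal(ncol(tr$matrix), unname(counts[fam]))
    expect_equal(nrow(tr$matrix), seg$end - seg$start)
  }
  all4 <- extract_tracks(sm, seg)
  expect_equal(ncol(all4$matrix), 606L)
  # deterministic enumeration order
  again <- extract_tracks(sm, seg)
  expect_identical(colnames(all4$matrix), colnames(again$matrix))
  expect_identical(colnames(all4$matrix)[1], "SA:HumerusLeft:phi")
  # JCD excludes the reference joint from pair enumeration
  expect_false(any(grepl("SpineMid", grep("^JCD", colnames(all4$matrix),
                                          value = TRUE))))
  # track values respect the family ranges
  expect_true(all(all4$matrix[, all4$family == "ED"] >= 0))
  jcd <- all4$matrix[, all4$family == "JCD"]
  expect_true(all(jcd >= 0 & jcd <= 2))
  expect_true(all(all4$matrix[, all4$family == "JTA"] >= 0))
  th <- all4$matrix[, grepl(":theta$", colnames(all4$matrix))]
  expect_true(all(th >= 0 & th <= pi))

  bad <- seg; bad$end <- n_frames(sm) + 5L
  expect_error(extract_tracks(sm, bad), class = "frailmotion_bounds_error")
})

test_that("bin-mean aggregation matches a loop-based oracle", {
  expect_equal(aggregate_resample(c(1, 2, 3, 4), 2), c(1.5, 3.5))
  expect_equal(aggregate_resample(rnorm(10) * 0 + 7, 3), rep(7, 3))
  x <- rnorm(25)
  expect_equal(aggregate_resample(x, 1), mean(x))

  # remainder frames go to the leading bins: 10 frames, 3 bins -> 4,3,3
  x <- rnorm(10)
  oracle <- c(mean(x[1:4]), mean(x[5:7]), mean(x[8:10]))
  expect_equal(aggregate_resample(x, 3), oracle)

  expect_error(aggregate_resample(1:3, 4),
               class = "frailmotion_aggregation_error")
  expect_error(aggregate_resample(1:3, 0),
               class = "frailmotion_validation_error")
})

test_that("histogram aggregation yields in-range probabilities", {
  x <- c(0.1, 0.2, 0.6, 0.9)
  h <- aggregate_histogram(x, 2, c(0, 1))
  expect_equal(h, c(0.5, 0.5))
  expect_equal(sum(aggregate_histogram(rnorm(100), 7, c(-5, 5))), 1)
  expect_equal(aggregate_histogram(rep(0.5, 8), 4, c(0, 1)),
               c(0, 0, 1, 0))
  # out-of-range samples lower the total but not the denominator
  h2 <- aggregate_histogram(c(x, 5, -3), 2, c(0, 1))
  expect_equal(sum(h2), 4 / 6)
  # the upper boundary falls in the last bin
  expect_equal(aggregate_histogram(c(0, 1), 4, c(0, 1)),
               c(0.5, 0, 0, 0.5))
  # uniform samples fill bins evenly (3-sigma binomial tolerance)
  withr::with_seed(13, {
    u <- runif(2000)
    h3 <- aggregate_histogram(u, 4, c(0, 1))
    tol <- 3 * sqrt(0.25 * 0.75 / 2000)
    expect_true(all(abs(h3 - 0.25) < tol))
  })
  expect_error(aggregate_histogram(x, 3, c(1, 1)),
               class = "frailmotion_validation_error")
})

test_that("concatenated feature-vector length obeys the count identity", {
  g <- generate_recording("sit_to_stand", seed = 32)
  tracks <- segment_tracks(g$recording)
  v <- build_feature_vector(tracks, nb = 20)
  expect_length(v, 12120)
  expect_length(v, expected_feature_length(nb = 20))

  sa_only <- extract_tracks(smooth_recording(g$recording),
                            attr(tracks, "segment"), families = "SA")
  expect_length(build_feature_vector(sa_only, nb = 5), 80)

  # identity holds for every family subset and bin count
  fams <- list("SA", "ED", c("JCD", "JTA"), c("SA", "ED", "JCD", "JTA"))
  for (f in fams) for (nb in c(1, 5, 20)) {
    tr <- extract_tracks(smooth_recording(g$recording),
                         attr(tracks, "segment"), families = f)
    expect_length(build_feature_vector(tr, nb = nb),
                  expected_feature_length(f, nb = nb))
  }

  empty <- tracks; empty$matrix <- tracks$matrix[, 0]; empty$family <- character(0)
  expect_error(build_feature_vector(empty),
               class = "frailmotion_validation_error")
})

test_that("standard scaling fits on the training rows only", {
  f <- tibble::tibble(subject_id = sprintf("S%d", 1:6),
                      `ED:a-b:b01` = c(1, 2, 3, 10, 20, 30),
                      `ED:a-c:b01` = rep(4, 6))
  sc <- standard_scale(f, fit_rows = 1:3)
  expect_equal(mean(sc$`ED:a-b:b01`[1:3]), 0, tolerance = 1e-12)
  expect_equal(sd(sc$`ED:a-b:b01`[1:3]), 1, tolerance = 1e-12)
  # constant column maps to zero everywhere
  expect_equal(sc$`ED:a-c:b01`, rep(0, 6))
  # held-out rows are transformed with the training parameters
  expect_equal(sc$`ED:a-b:b01`[4:6], (c(10, 20, 30) - 2) / 1,
               tolerance = 1e-12)
  params <- attr(sc, "scaling")
  expect_equal(unname(params$mean[params$feature == "ED:a-b:b01"]), 2)
  expect_error(standard_scale(f, fit_rows = integer(0)),
               class = "frailmotion_validation_error")
})

test_that("feature tables are rectangular with train-fitted histogram
           ranges", {
  coh <- quick_sts_cohort(n_per_class = 3, seed = 77)
  ts <- extract_track_sets(coh$recordings)
  train_ids <- coh$subjects$subject_id[c(1, 2, 4)]
  ft <- build_feature_table(ts, nb = 5, fit_subjects = train_ids)
  expect_equal(nrow(ft), 6)
  expect_length(feature_columns <- setdiff(names(ft), "subject_id"),
                expected_feature_length(nb = 5))
  expect_false(any(!is.finite(as.matrix(ft[feature_columns]))))

  # oracle: the stored range of one histogram track equals the min/max of
  # that track over the fitting subjects only
  rng <- attr(ft, "hist_ranges")$sit_to_stand
  nm <- names(rng)[1]
  vals <- unlist(lapply(which(ts$subject_id %in% train_ids), function(i) {
    ts$tracks[[i]]$matrix[, nm]
  }))
  expect_equal(unname(rng[[nm]]), c(min(vals), max(vals)), tolerance = 1e-12)
})
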