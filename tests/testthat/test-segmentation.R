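test_that("gaussian smoothing preserves constants and the impulse response
           is the renormalized kernel", {
  expect_equal(gaussian_smooth(rep(3.2, 50), window = 9), rep(3.2, 50))

  # unit impulse in the interior reproduces the normalized kernel
  x <- rep(0, 21); x[11] <- 1
  sm <- gaussian_smooth(x, window = 5, sigma = 1)
  kern <- dnorm(-2:2, sd = 1); kern <- kern / sum(kern)
  expect_equal(sm[9:13], kern, tolerance = 1e-12)

  expect_error(gaussian_smooth(1:10, window = 4),
               class = "frailmotion_validation_error")
  expect_error(gaussian_smooth(1:10, window = 11),
               class = "frailmotion_validation_error")
  expect_error(gaussian_smooth(1:10, window = 5, sigma = 0),
               class = "frailmotion_validation_error")
})

test_that("smoothing reduces the variance of a noisy sinusoid", {
  withr::with_seed(5, {
    worse <- 0
    for (i in 1:100) {
      x <- sin(2 * pi * (1:300) / 60)
      noisy <- x + rnorm(300, 0, 0.3)
      sm <- gaussian_smooth(noisy, window = 9, sigma = 9 / 5)
      if (var(sm - x) >= var(noisy - x)) worse <- worse + 1
    }
    expect_equal(worse, 0)
  })
})

test_that("AMPD finds the analytic peaks of a clean periodic signal", {
  x <- sin(2 * pi * 5 * (0:499) / 500)
  peaks <- ampd_extrema(x, "maxima")
  expect_length(peaks, 5)
  expect_true(all(abs(peaks - c(26, 126, 226, 326, 426)) <= 1))
  troughs <- ampd_extrema(x, "minima")
  expect_length(troughs, 5)
  expect_true(all(abs(troughs - c(76, 176, 276, 376, 476)) <= 1))

  expect_identical(ampd_extrema(rep(1, 100), "maxima"), integer(0))
  expect_error(ampd_extrema(1:7), class = "frailmotion_validation_error")
})

test_that("AMPD peak count is robust to jitter and obeys negation duality", {
  # a trial-like trace: starts and ends at rest (metric troughs)
  x0 <- -cos(2 * pi * 5 * (0:499) / 500)
  n0 <- length(ampd_extrema(x0, "maxima"))
  expect_equal(n0, 5)
  noise_sd <- sd(x0) / sqrt(10)      # SNR 10 in power
  for (s in 1:50) {
    withr::with_seed(s, xn <- x0 + rnorm(500, 0, noise_sd))
    expect_length(ampd_extrema(xn, "maxima"), n0)
  }
  # duality: maxima of -x are the minima of x
  withr::with_seed(8, {
    for (i in 1:10) {
      y <- sin(2 * pi * runif(1, 3, 8) * (0:299) / 300) +
        rnorm(300, 0, 0.05)
      expect_identical(ampd_extrema(-y, "maxima"),
                       ampd_extrema(y, "minima"))
    }
  })
})

test_that("cycle metrics use the documented joint pairs", {
  rec <- constant_recording(overrides = list(
    KneeLeft = c(0, 0, 0), SpineShoulder = c(0, 0.8, 0.6)))
  m <- cycle_metric(rec, smooth = FALSE)
  expect_s3_class(m, "cycle_metric")
  expect_equal(m$value, rep(1, n_frames(rec)))   # 3-4-5 triangle scaled
  expect_equal(attr(m, "source_joints"), c("KneeLeft", "SpineShoulder"))
  # smoothing preserves a constant metric
  expect_equal(cycle_metric(rec, smooth = TRUE)$value, rep(1, 20))

  gait <- constant_recording(exercise = "gait", overrides = list(
    AnkleLeft = c(-0.3, 0, 2), AnkleRight = c(0.3, 0, 2)))
  expect_equal(cycle_metric(gait, smooth = FALSE)$value, rep(0.6, 20))

  curl <- constant_recording(exercise = "arm_curl", dominant_hand = "left")
  expect_equal(attr(cycle_metric(curl, smooth = FALSE), "source_joints"),
               c("Head", "WristLeft"))
  curl_nh <- constant_recording(exercise = "arm_curl")
  expect_error(cycle_metric(curl_nh, smooth = FALSE),
               class = "frailmotion_configuration_error")
})

test_that("cycle isolation applies the per-exercise extremum rules", {
  # arm-curl rule on a pure sinusoid: max to next max = one period
  t <- 0:299
  period <- 60
  x <- 0.2 * cos(2 * pi * t / period) + 1
  seg <- isolate_cycles(x, exercise = "arm_curl")
  expect_lte(abs((seg$end - seg$start) - period), 1)

  # gait rule spans two metric oscillations (two steps = one gait cycle)
  seg_g <- isolate_cycles(x, exercise = "gait")
  expect_lte(abs((seg_g$end - seg_g$start) - 2 * period), 1)

  # sit-to-stand rule anchors on minima
  seg_s <- isolate_cycles(-x + 2, exercise = "sit_to_stand")
  expect_lte(abs((seg_s$end - seg_s$start) - period), 1)

  # n_cycles spans consecutive cycles
  seg3 <- isolate_cycles(x, exercise = "arm_curl", n_cycles = 3)
  expect_lte(abs((seg3$end - seg3$start) - 3 * period), 1)

  expect_error(isolate_cycles(rep(1, 100), exercise = "gait"),
               class = "frailmotion_cycle_error")
  # too few qualifying extrema for the requested span
  expect_error(isolate_cycles(x, exercise = "gait", n_cycles = 40),
               class = "frailmotion_cycle_error")
})

test_that("segments are invariant to metric offset and uniform scaling", {
  withr::with_seed(21, {
    x <- 0.3 * sin(2 * pi * (0:399) / 80) + rnorm(400, 0, 0.02) + 1
    seg <- isolate_cycles(x, exercise = "gait")
    seg_shift <- isolate_cycles(x + 5, exercise = "gait")
    seg_scale <- isolate_cycles(x * 3.7, exercise = "gait")
    expect_identical(c(seg$start, seg$end),
                     c(seg_shift$start, seg_shift$end))
    expect_identical(c(seg$start, seg$end),
                     c(seg_scale$start, seg_scale$end))
  })
})

test_that("low-prominence extrema are discarded before the rule applies", {
  # a small ripple riding on a large oscillation: the ripple extrema are
  # pruned at the default threshold, so one cycle spans the carrier period
  t <- 0:479
  x <- sin(2 * pi * t / 120) + 0.05 * sin(2 * pi * t / 15)
  seg <- isolate_cycles(x, exercise = "arm_curl", min_prominence = 0.2)
  expect_lte(abs((seg$end - seg$start) - 120), 3)
})

test_that("segmentation recovers the generator's cycle period within 5%", {
  errs <- c()
  for (ex in exercise_types()) {
    fps <- 30
    for (s in 1:12) {
      prof <- motion_profile(ex, frame_rate = fps,
                             duration = if (ex == "two_min_step") 20 else NULL)
      g <- generate_recording(ex, prof, seed = 1000 + s)
      sm <- smooth_recording(g$recording)
      seg <- isolate_cycles(cycle_metric(sm, smooth = FALSE), n_cycles = 3)
      est <- (seg$end - seg$start) / 3 / fps
      true_cycle <- if (ex %in% c("gait", "two_min_step")) {
        prof$cycle_period           # rule spans 2 metric periods = 1 cycle
      } else prof$cycle_period
      errs <- c(errs, abs(est - true_cycle) / true_cycle)
    }
  }
  expect_lt(median(errs), 0.05)
  expect_lt(max(errs), 0.15)
})
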