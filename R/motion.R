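#' Motion profile for the synthetic-recording generator
#'
#' Describes one subject's execution of one exercise: cycle period,
#' movement amplitude, sensor jitter, frame rate, recording length, slow
#' posture drift and dominant hand. Defaults follow the functional
#' assessment protocol: 30-s arm curl and sit-to-stand, a 4-m walk, and a
#' 2-min step test, captured at 30 Hz.
#'
#' `amplitude` is in meters and scales the exercise-specific excursion:
#' peak wrist arc displacement (arm curl), vertical trunk excursion
#' (sit-to-stand), step length (gait) and peak foot lift (step test).
#'
#' @param exercise One of the four exercise codes.
#' @param cycle_period Movement cycle period in seconds (> 0). A gait cycle
#'   is two steps.
#' @param amplitude Movement amplitude in meters (> 0).
#' @param noise_sd Per-axis Gaussian jitter in meters (>= 0); the
#'   frame-to-frame sensor noise that creates spurious local extrema.
#' @param frame_rate Sampling rate in Hz.
#' @param duration Recording length in seconds; must cover at least 3
#'   cycles. `NULL` uses the protocol default (30 s, 30 s, the time to walk
#'   4 m, 120 s).
#' @param drift Slow posture drift along the depth axis in m/s.
#' @param dominant_hand `"left"` or `"right"` (arm curl).
#' @param quantize Optional coordinate quantization step in meters
#'   (0 = off); mimics the stepwise raw-sensor traces.
#' @return A `motion_profile` list.
#' @export
motion_profile <- function(exercise,
                           cycle_period = NULL, amplitude = NULL,
                           noise_sd = 0.008, frame_rate = 30,
                           duration = NULL, drift = 0,
                           dominant_hand = "right", quantize = 0) {
  assert_exercise(exercise)
  defaults <- list(
    arm_curl = list(period = 2.0, amplitude = 0.50, duration = 30),
    sit_to_stand = list(period = 3.0, amplitude = 0.30, duration = 30),
    gait = list(period = 1.1, amplitude = 0.50, duration = NA),
    two_min_step = list(period = 1.2, amplitude = 0.25, duration = 120)
  )[[exercise]]
  cycle_period <- cycle_period %||% defaults$period
  amplitude <- amplitude %||% defaults$amplitude
  if (is.null(duration)) {
    duration <- if (exercise == "gait") {
      4 / (2 * amplitude / cycle_period)  # time to walk 4 m
    } else defaults$duration
  }
  if (cycle_period <= 0 || amplitude <= 0 || noise_sd < 0 || frame_rate <= 0) {
    abort("Profile parameters out of range",
          class = "frailmotion_validation_error")
  }
  if (duration < 3 * cycle_period) {
    abort("`duration` must cover at least 3 cycle periods",
          class = "frailmotion_validation_error")
  }
  structure(list(exercise = exercise, cycle_period = cycle_period,
                 amplitude = amplitude, noise_sd = noise_sd,
                 frame_rate = frame_rate, duration = duration,
                 drift = drift, dominant_hand = dominant_hand,
                 quantize = quantize),
            class = "motion_profile")
}

# Neutral standing template, meters; x lateral, y vertical (up from the
# floor), z depth from the camera. Subject centred at z = 2.5 m.
base_pose <- function(z0 = 2.5) {
  p <- rbind(
    SpineBase = c(0, 1.00, 0), SpineMid = c(0, 1.25, 0),
    Neck = c(0, 1.55, 0), Head = c(0, 1.70, 0),
    ShoulderLeft = c(-0.20, 1.45, 0), ElbowLeft = c(-0.25, 1.17, 0),
    WristLeft = c(-0.27, 0.92, 0), HandLeft = c(-0.27, 0.86, 0),
    ShoulderRight = c(0.20, 1.45, 0), ElbowRight = c(0.25, 1.17, 0),
    WristRight = c(0.27, 0.92, 0), HandRight = c(0.27, 0.86, 0),
    HipLeft = c(-0.10, 0.95, 0), KneeLeft = c(-0.11, 0.50, 0),
    AnkleLeft = c(-0.11, 0.08, 0), FootLeft = c(-0.11, 0.03, -0.12),
    HipRight = c(0.10, 0.95, 0), KneeRight = c(0.11, 0.50, 0),
    AnkleRight = c(0.11, 0.08, 0), FootRight = c(0.11, 0.03, -0.12),
    SpineShoulder = c(0, 1.45, 0),
    HandTipLeft = c(-0.27, 0.79, 0), ThumbLeft = c(-0.24, 0.84, 0.02),
    HandTipRight = c(0.27, 0.79, 0), ThumbRight = c(0.24, 0.84, 0.02)
  )
  p[, 3] <- p[, 3] + z0
  p[kinect_joints(), ]
}

#' Generate a synthetic exercise recording with ground truth
#'
#' Builds a 25-joint sequence from a neutral standing/sitting template with
#' sinusoidal joint trajectories of the requested period and amplitude,
#' plus white Gaussian jitter, optional posture drift and optional
#' coordinate quantization. The kinematics are keyed to the
#' cycle-identification metrics: the arm curl modulates the head-wrist
#' distance, sit-to-stand the knee-spine distance, and gait/step move the
#' ankles in anti-phase.
#'
#' The returned ground truth carries the analytic extrema of the metric and
#' the cycle boundaries implied by the per-exercise rule, for use as an
#' oracle in tests and QC.
#'
#' @param exercise Exercise code (must match `profile$exercise` if the
#'   profile carries one).
#' @param profile A [motion_profile()].
#' @param seed Integer seed (jitter and quantization are the only random
#'   elements).
#' @return A list with `recording` (an `exercise_recording`) and
#'   `ground_truth` (list: `metric_period_s`, `metric_maxima`,
#'   `metric_minima` — frame indices — and `segment` = the true
#'   `[start, end)` of the first cycle).
#' @export
generate_recording <- function(exercise, profile = motion_profile(exercise),
                               seed = 1L) {
  assert_exercise(exercise)
  if (!identical(profile$exercise, exercise)) {
    abort("`profile` was built for a different exercise",
          class = "frailmotion_validation_error")
  }
  nf <- max(8L, round(profile$duration * profile$frame_rate))
  t <- (seq_len(nf) - 1L) / profile$frame_rate
  pose <- base_pose()
  coords <- array(rep(pose, each = nf), dim = c(nf, 25L, 3L),
                  dimnames = list(NULL, kinect_joints(), c("x", "y", "z")))
  omega <- 2 * pi / profile$cycle_period
  a <- profile$amplitude

  move <- function(joints, axis, delta) {
    for (j in joints) coords[, j, axis] <<- coords[, j, axis] + delta
  }

  # Recordings start while the movement is already underway (the sensor is
  # switched on mid-exercise), so the first rule anchor of the cycle metric
  # lies in the interior of the series, a quarter period in.
  phase0 <- pi / 2

  if (exercise == "arm_curl") {
    side <- if (profile$dominant_hand == "left") "Left" else "Right"
    elbow <- pose[paste0("Elbow", side), ]
    forearm <- 0.26
    beta_max <- min(2.4, a / forearm)      # curl arc angle, radians
    beta <- beta_max * (1 - cos(omega * t - phase0)) / 2
    wrist_y <- elbow[2] - forearm * cos(beta)
    wrist_z <- elbow[3] - forearm * sin(beta)
    hand_joints <- paste0(c("Wrist", "Hand", "HandTip", "Thumb"), side)
    wrist0 <- pose[paste0("Wrist", side), ]
    move(hand_joints, 2L, wrist_y - wrist0[2])
    move(hand_joints, 3L, wrist_z - wrist0[3])
  } else if (exercise == "sit_to_stand") {
    dy <- -a * (1 + cos(omega * t - phase0)) / 2  # 0 = standing, -a = seated
    trunk <- c("SpineBase", "SpineMid", "SpineShoulder", "Neck", "Head",
               "HipLeft", "HipRight", "ShoulderLeft", "ShoulderRight",
               "ElbowLeft", "ElbowRight", "WristLeft", "WristRight",
               "HandLeft", "HandRight", "HandTipLeft", "HandTipRight",
               "ThumbLeft", "ThumbRight")
    move(trunk, 2L, dy)
    move(c("SpineBase", "HipLeft", "HipRight"), 3L, 0.4 * dy / a * -0.1)
  } else {                                  # gait and two_min_step
    phase <- sin(omega * t)
    left_leg <- c("KneeLeft", "AnkleLeft", "FootLeft")
    right_leg <- c("KneeRight", "AnkleRight", "FootRight")
    if (exercise == "gait") {
      v <- 2 * a / profile$cycle_period     # walking speed
      move(kinect_joints(), 3L, 2.0 - v * t)  # start deep, walk toward camera
      move(c("AnkleLeft", "FootLeft"), 3L, (a / 2) * phase)
      move(c("AnkleRight", "FootRight"), 3L, -(a / 2) * phase)
      move("KneeLeft", 3L, (a / 4) * phase)
      move("KneeRight", 3L, -(a / 4) * phase)
      move(c("WristLeft", "HandLeft"), 3L, -0.1 * phase)
      move(c("WristRight", "HandRight"), 3L, 0.1 * phase)
    } else {
      move(c("AnkleLeft", "FootLeft"), 2L, a * (1 + phase) / 2)
      move(c("AnkleRight", "FootRight"), 2L, a * (1 - phase) / 2)
      move("KneeLeft", 2L, a * (1 + phase) / 4)
      move("KneeRight", 2L, a * (1 - phase) / 4)
    }
  }

  if (profile$drift != 0) move(kinect_joints(), 3L, profile$drift * t)

  withr::with_seed(seed, {
    if (profile$noise_sd > 0) {
      coords <- coords + array(rnorm(length(coords), 0, profile$noise_sd),
                               dim = dim(coords))
    }
  })
  if (profile$quantize > 0) {
    coords <- round(coords / profile$quantize) * profile$quantize
  }

  df <- tibble::tibble(
    time = rep(t, 25L),
    joint = rep(kinect_joints(), each = nf),
    x = as.vector(coords[, , 1L]),
    y = as.vector(coords[, , 2L]),
    z = as.vector(coords[, , 3L])
  )
  rec <- as_recording(df, subject_id = "synthetic", exercise = exercise,
                      dominant_hand = profile$dominant_hand,
                      frame_rate_hint = profile$frame_rate)
  list(recording = rec,
       ground_truth = motion_ground_truth(exercise, profile, nf))
}

# Analytic metric extrema (frame indices, 1-based) and the true first-cycle
# segment under the per-exercise rule.
motion_ground_truth <- function(exercise, profile, nf) {
  fps <- profile$frame_rate
  Tc <- profile$cycle_period
  dur <- (nf - 1) / fps
  grid <- function(times) {
    f <- round(times * fps) + 1L
    f[f >= 1 & f <= nf]
  }
  if (exercise %in% c("arm_curl", "sit_to_stand")) {
    metric_period <- Tc
    # phase0 = pi/2 puts the first anchor a quarter period into the series
    anchors <- grid(seq(Tc / 4, dur, by = Tc))        # arm: maxima; STS: minima
    others <- grid(seq(3 * Tc / 4, dur, by = Tc))
    maxima <- if (exercise == "arm_curl") anchors else others
    minima <- if (exercise == "arm_curl") others else anchors
    seg <- c(anchors[1], anchors[2] + 1L)
  } else {
    metric_period <- Tc / 2
    maxima <- grid(seq(Tc / 4, dur, by = Tc / 2))
    minima <- grid(seq(0, dur, by = Tc / 2))
    seg <- c(maxima[1], maxima[3] + 1L)
  }
  list(metric_period_s = metric_period,
       metric_maxima = maxima, metric_minima = minima,
       segment = seg)
}
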