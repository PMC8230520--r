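#' Build an exercise recording from a tidy frame table
#'
#' An exercise recording is a tibble in long format — one row per joint per
#' frame, columns `frame`, `time`, `joint`, `x`, `y`, `z` — carrying the
#' subject and protocol metadata as attributes. Coordinates are in meters in
#' the camera frame (x lateral, y vertical, z depth); `time` is in seconds
#' and strictly increasing across frames; frames are numbered from 1.
#'
#' @param data A data frame with columns `time` (or `timestamp`), `joint`,
#'   `x`, `y`, `z`; one row per joint per frame.
#' @param subject_id Subject identifier.
#' @param exercise One of `r paste(exercise_types(), collapse = ", ")`.
#' @param dominant_hand `"left"` or `"right"`; required for `arm_curl`
#'   (the cycle metric tracks the dominant wrist).
#' @param repetition Repetition index (gait is recorded three times).
#' @param frame_rate_hint Optional nominal frame rate in Hz.
#' @param validate Check invariants (>= 2 frames, all 25 joints per frame,
#'   finite coordinates, strictly increasing times).
#' @return A tibble of class `exercise_recording`.
#' @seealso [read_recording()], [joint_track()], [generate_recording()]
#' @export
as_recording <- function(data, subject_id, exercise,
                         dominant_hand = NULL, repetition = 1L,
                         frame_rate_hint = NULL, validate = TRUE) {
  assert_exercise(exercise)
  if (!is.null(dominant_hand) &&
      !dominant_hand %in% c("left", "right")) {
    abort("`dominant_hand` must be \"left\" or \"right\"",
          class = "frailmotion_validation_error")
  }
  data <- tibble::as_tibble(data)
  if ("timestamp" %in% names(data) && !"time" %in% names(data)) {
    data <- dplyr::rename(data, time = "timestamp")
  }
  need <- c("time", "joint", "x", "y", "z")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Recording table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "frailmotion_format_error")
  }
  for (col in need) data[[col]] <- unname(data[[col]])
  times <- sort(unique(data$time))
  data$frame <- match(data$time, times)
  data <- dplyr::arrange(data, frame, match(joint, kinect_joints()))
  data <- data[, c("frame", "time", "joint", "x", "y", "z")]

  rec <- tibble::new_tibble(
    data,
    class = "exercise_recording",
    subject_id = subject_id,
    exercise = exercise,
    dominant_hand = dominant_hand,
    repetition = as.integer(repetition),
    frame_rate_hint = frame_rate_hint
  )
  if (validate) validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  times <- unique(rec$time)
  if (length(times) < 2) {
    abort("Recording has fewer than 2 usable frames",
          class = "frailmotion_empty_recording_error")
  }
  if (any(diff(times) <= 0)) {
    abort("Timestamps must be strictly increasing",
          class = "frailmotion_validation_error")
  }
  unknown <- setdiff(unique(rec$joint), kinect_joints())
  if (length(unknown) > 0) {
    abort(paste0("Unknown joint name(s): ", paste(unknown, collapse = ", ")),
          class = "frailmotion_format_error")
  }
  counts <- table(rec$frame)
  if (any(counts != 25)) {
    abort("Every frame must contain all 25 joints (use read_recording() to impute or drop incomplete frames)",
          class = "frailmotion_validation_error")
  }
  if (!all(is.finite(rec$x) & is.finite(rec$y) & is.finite(rec$z))) {
    abort("All coordinates must be finite", class = "frailmotion_validation_error")
  }
  invisible(rec)
}

#' @export
print.exercise_recording <- function(x, ...) {
  cat(sprintf("<exercise_recording> subject %s, %s, %d frames (%.1f s)\n",
              attr(x, "subject_id"), attr(x, "exercise"),
              n_frames(x), diff(range(x$time))))
  NextMethod()
}

#' Number of frames in a recording
#' @param recording An `exercise_recording`.
#' @return Integer frame count.
#' @export
n_frames <- function(recording) {
  length(unique(recording$frame))
}

# Dense numeric view: list(timestamps, coords[frame, joint, axis]) with
# joints in kinect_joints() order. All numeric kernels work off this.
recording_array <- function(recording) {
  joints <- kinect_joints()
  nf <- n_frames(recording)
  coords <- array(NA_real_, dim = c(nf, 25L, 3L),
                  dimnames = list(NULL, joints, c("x", "y", "z")))
  idx <- cbind(recording$frame, match(recording$joint, joints))
  coords[cbind(idx, 1L)] <- recording$x
  coords[cbind(idx, 2L)] <- recording$y
  coords[cbind(idx, 3L)] <- recording$z
  list(timestamps = unique(recording$time), coords = coords)
}

# Inverse of recording_array(), keeping metadata from a template recording.
array_recording <- function(arr, template) {
  nf <- dim(arr$coords)[1]
  df <- tibble::tibble(
    time = rep(arr$timestamps, each = 25L),
    joint = rep(kinect_joints(), nf),
    x = as.vector(t(arr$coords[, , 1L])),
    y = as.vector(t(arr$coords[, , 2L])),
    z = as.vector(t(arr$coords[, , 3L]))
  )
  as_recording(df,
               subject_id = attr(template, "subject_id"),
               exercise = attr(template, "exercise"),
               dominant_hand = attr(template, "dominant_hand"),
               repetition = attr(template, "repetition"),
               frame_rate_hint = attr(template, "frame_rate_hint"),
               validate = FALSE)
}

#' Per-axis trajectory of a single joint
#'
#' @param recording An `exercise_recording`.
#' @param joint A joint name from [kinect_joints()].
#' @return A tibble with columns `frame`, `time`, `x`, `y`, `z`; one row per
#'   frame, ordered by time.
#' @examples
#' rec <- generate_recording("sit_to_stand", motion_profile("sit_to_stand"), seed = 1)
#' joint_track(rec$recording, "SpineShoulder")
#' @export
joint_track <- function(recording, joint) {
  assert_joint(joint)
  out <- recording[recording$joint == joint,
                   c("frame", "time", "x", "y", "z")]
  tibble::as_tibble(out)[order(out$frame), ]
}

#' Estimated frame rate of a recording (Hz)
#' @param recording An `exercise_recording`.
#' @return Median frame rate in Hz.
#' @export
frame_rate <- function(recording) {
  ts <- unique(recording$time)
  1 / median(diff(ts))
}

#' Load report attached by the reader
#'
#' @param recording An `exercise_recording` returned by [read_recording()].
#' @return A tibble with `n_frames`, `n_imputed`, `n_dropped` (NULL for
#'   recordings not built by the reader).
#' @export
load_report <- function(recording) {
  attr(recording, "load_report")
}
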