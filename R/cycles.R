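#' Cycle-identification distance metric of an exercise
#'
#' Each exercise is tracked through one per-frame 3D inter-joint distance
#' whose oscillation delimits movement cycles:
#' \describe{
#'   \item{arm_curl}{Head to the dominant-side wrist (the head is a stable
#'     reference; the wrist approaches it at the top of the curl).}
#'   \item{sit_to_stand}{KneeLeft to SpineShoulder (maximal when standing,
#'     minimal when seated).}
#'   \item{gait, two_min_step}{Left to right ankle (maximal at full step
#'     separation or highest foot lift).}
#' }
#' The distance is computed on the smoothed sequence (see
#' [smooth_recording()]); pass `smooth = FALSE` if the recording is already
#' smoothed.
#'
#' @param recording An `exercise_recording`.
#' @param smooth Smooth the joint trajectories first (default `TRUE`).
#' @param window,sigma Smoothing parameters forwarded to
#'   [smooth_recording()].
#' @return A tibble of class `cycle_metric` with columns `frame`, `time`,
#'   `value` (meters) and attributes `exercise` and `source_joints`.
#' @export
cycle_metric <- function(recording, smooth = TRUE,
                         window = NULL, sigma = NULL) {
  exercise <- attr(recording, "exercise")
  joints <- switch(exercise,
    arm_curl = {
      hand <- attr(recording, "dominant_hand")
      if (is.null(hand)) {
        abort("arm_curl cycle metric needs `dominant_hand` on the recording",
              class = "frailmotion_configuration_error")
      }
      c("Head", if (hand == "left") "WristLeft" else "WristRight")
    },
    sit_to_stand = c("KneeLeft", "SpineShoulder"),
    gait = c("AnkleLeft", "AnkleRight"),
    two_min_step = c("AnkleLeft", "AnkleRight")
  )
  if (smooth) recording <- smooth_recording(recording, window, sigma)
  arr <- recording_array(recording)
  p1 <- arr$coords[, joints[1], ]
  p2 <- arr$coords[, joints[2], ]
  d <- sqrt(rowSums((p2 - p1)^2))
  tibble::new_tibble(
    tibble::tibble(frame = seq_along(d), time = arr$timestamps, value = d),
    class = "cycle_metric",
    exercise = exercise,
    source_joints = joints
  )
}

#' Isolate movement cycles from a distance metric
#'
#' Detects the significant maxima and minima of the metric with
#' [ampd_extrema()], discards extrema of low prominence, and applies the
#' per-exercise start/stop rule:
#' \describe{
#'   \item{arm_curl}{from a global maximum, past a global minimum, to the
#'     next global maximum (arm extended - curled - extended);}
#'   \item{sit_to_stand}{from a global minimum, past a global maximum, to
#'     the next global minimum (seated - standing - seated);}
#'   \item{gait, two_min_step}{from a global maximum to its second
#'     subsequent global maximum (two steps = one cycle).}
#' }
#' The prominence of an extremum is the absolute difference between its
#' value and that of the nearest opposite-polarity extremum; extrema with
#' prominence below `min_prominence` times the metric range are treated as
#' jitter and discarded before the rule is applied. After discarding,
#' consecutive same-polarity extrema are collapsed to the most extreme one
#' (earliest frame on ties). The returned segment covers the first
#' `n_cycles` consecutive cycles.
#'
#' @param metric A `cycle_metric` (or a numeric vector together with
#'   `exercise`).
#' @param exercise Exercise tag; taken from the metric when absent.
#' @param n_cycles Number of consecutive cycles to span (>= 1).
#' @param min_prominence Prominence threshold as a fraction of the metric
#'   range, in `[0, 1)`.
#' @return An object of class `cycle_segment`: a list with `start`
#'   (inclusive), `end` (exclusive), `n_cycles`, and the annotated extrema
#'   table. Frame indices are 1-based; the segment is the half-open
#'   interval `[start, end)`.
#' @export
isolate_cycles <- function(metric, exercise = NULL, n_cycles = 1L,
                           min_prominence = 0.2) {
  if (inherits(metric, "cycle_metric")) {
    exercise <- exercise %||% attr(metric, "exercise")
    values <- metric$value
  } else {
    values <- as.numeric(metric)
  }
  assert_exercise(exercise)
  if (n_cycles < 1) {
    abort("`n_cycles` must be >= 1", class = "frailmotion_validation_error")
  }

  maxima <- ampd_extrema(values, "maxima")
  minima <- ampd_extrema(values, "minima")
  if (length(maxima) == 0 || length(minima) == 0) {
    abort_cycles(exercise, length(maxima), length(minima))
  }

  ext <- rbind(
    data.frame(frame = maxima, polarity = "max"),
    data.frame(frame = minima, polarity = "min")
  )
  ext <- ext[order(ext$frame), ]
  ext$value <- values[ext$frame]

  # prominence against the nearest opposite-polarity extremum
  rng <- diff(range(values))
  opp <- ifelse(ext$polarity == "max", "min", "max")
  ext$prominence <- vapply(seq_len(nrow(ext)), function(i) {
    others <- ext[ext$polarity == opp[i], ]
    j <- which.min(abs(others$frame - ext$frame[i]))
    abs(ext$value[i] - others$value[j])
  }, numeric(1))
  ext$used <- ext$prominence >= min_prominence * rng
  kept <- ext[ext$used, ]
  kept <- collapse_polarity_runs(kept)

  seg <- apply_cycle_rule(kept, exercise, n_cycles)
  if (is.null(seg)) {
    abort_cycles(exercise, sum(kept$polarity == "max"),
                 sum(kept$polarity == "min"))
  }
  # refine the two boundary extrema by a parabolic vertex fit: averaging
  # the metric over a neighbourhood beats the raw argmax, whose position
  # wanders under jitter on the flat top of a smooth extremum
  half <- if (nrow(kept) > 1) {
    max(3L, round(median(diff(kept$frame)) / 4))
  } else 3L
  seg <- vapply(seg, refine_extremum, integer(1),
                values = values, half = half)
  structure(
    list(start = seg[1], end = seg[2] + 1L, n_cycles = as.integer(n_cycles),
         extrema = tibble::as_tibble(ext)),
    class = "cycle_segment"
  )
}

abort_cycles <- function(exercise, n_max, n_min) {
  abort(sprintf(
    "Cycle detection failed for %s: found %d qualifying maxima and %d minima",
    exercise, n_max, n_min), class = "frailmotion_cycle_error")
}

# After prominence filtering the max/min alternation can break; keep the
# most extreme of each same-polarity run (earliest frame on ties).
collapse_polarity_runs <- function(ext) {
  if (nrow(ext) == 0) return(ext)
  run <- cumsum(c(TRUE, ext$polarity[-1] != ext$polarity[-nrow(ext)]))
  keep <- vapply(split(seq_len(nrow(ext)), run), function(idx) {
    v <- ext$value[idx]
    best <- if (ext$polarity[idx[1]] == "max") which.max(v) else which.min(v)
    idx[best]
  }, integer(1))
  ext[sort(keep), ]
}

apply_cycle_rule <- function(ext, exercise, n_cycles) {
  anchor <- switch(exercise,
                   arm_curl = "max", sit_to_stand = "min",
                   gait = "max", two_min_step = "max")
  span <- switch(exercise,
                 arm_curl = n_cycles, sit_to_stand = n_cycles,
                 gait = 2L * n_cycles, two_min_step = 2L * n_cycles)
  anchors <- ext$frame[ext$polarity == anchor]
  # the anchor list alternates with the opposite extrema after collapsing,
  # so "the n-th subsequent anchor" passes through n opposite extrema
  if (length(anchors) < span + 1) return(NULL)
  c(anchors[1], anchors[1 + span])
}

# Least-squares parabola through values[idx +/- half]; returns the vertex
# frame when it falls inside the window, else the original index.
refine_extremum <- function(idx, values, half) {
  lo <- max(1L, idx - half); hi <- min(length(values), idx + half)
  t <- lo:hi
  if (length(t) < 5) return(as.integer(idx))
  fit <- stats::lm.fit(cbind(1, t, t^2), values[t])
  a <- fit$coefficients[3]; b <- fit$coefficients[2]
  if (!is.finite(a) || a == 0) return(as.integer(idx))
  vertex <- -b / (2 * a)
  if (vertex < lo || vertex > hi) return(as.integer(idx))
  as.integer(round(vertex))
}

#' @export
print.cycle_segment <- function(x, ...) {
  cat(sprintf("<cycle_segment> [%d, %d) spanning %d cycle(s), %d frames\n",
              x$start, x$end, x$n_cycles, x$end - x$start))
  invisible(x)
}

#' Frames covered by a cycle segment
#' @param segment A `cycle_segment`.
#' @return Integer vector `start .. end - 1`.
#' @export
segment_frames <- function(segment) {
  seq.int(segment$start, segment$end - 1L)
}

#' Plot a cycle metric with detected extrema and segment borders
#'
#' Quality-control view of the segmentation stage: the metric trace, the
#' AMPD extrema (filled = retained after the prominence filter) and the
#' segment borders as dashed lines.
#'
#' @param object A `cycle_metric`.
#' @param segment Optional `cycle_segment` from [isolate_cycles()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.cycle_metric <- function(object, segment = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = frame, y = value)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(
      x = "frame", y = "distance metric [m]",
      title = attr(object, "exercise"),
      subtitle = paste(attr(object, "source_joints"), collapse = " – ")
    ) +
    ggplot2::theme_minimal()
  if (!is.null(segment)) {
    ext <- segment$extrema
    p <- p +
      ggplot2::geom_point(
        data = ext,
        ggplot2::aes(x = frame, y = value, colour = polarity, alpha = used),
        size = 2.5) +
      ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.25)) +
      ggplot2::scale_colour_manual(values = c(max = "firebrick",
                                              min = "forestgreen")) +
      ggplot2::geom_vline(xintercept = c(segment$start, segment$end - 1L),
                          linetype = "dashed")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
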