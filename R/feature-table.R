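#' Default aggregation scheme per feature family
#'
#' Bin-mean resampling preserves the waveform of angle and distance tracks;
#' histogram aggregation summarises the value distribution of the
#' dissimilarity and area tracks. Both aggregators are available for every
#' family — override by passing a named vector to
#' [build_feature_table()].
#'
#' @return Named character vector mapping family to
#'   `"resample"`/`"histogram"`.
#' @export
default_aggregation <- function() {
  c(SA = "resample", ED = "resample", JCD = "histogram", JTA = "histogram")
}

#' Expected concatenated feature-vector length
#'
#' With all four families and the default 21 active joints the per-exercise
#' track counts are 16 (SA), 210 (ED), 190 (JCD) and 190 (JTA), so the
#' concatenated vector has `nb * 606` entries per exercise.
#'
#' @param families Subset of `c("SA", "ED", "JCD", "JTA")`.
#' @param nb Number of aggregation bins.
#' @param na Number of active joints.
#' @param n_exercises Number of concatenated exercises.
#' @return Integer vector length.
#' @examples
#' expected_feature_length(c("SA", "ED", "JCD", "JTA"), nb = 20)  # 12120
#' @export
expected_feature_length <- function(families = c("SA", "ED", "JCD", "JTA"),
                                    nb = 20, na = 21, n_exercises = 1) {
  counts <- c(SA = 16, ED = na * (na - 1) / 2,
              JCD = (na - 1) * (na - 2) / 2, JTA = (na - 1) * (na - 2) / 2)
  as.integer(n_exercises * nb * sum(counts[families]))
}

#' Segment a recording and extract its feature tracks
#'
#' Convenience wrapper chaining the per-recording stages: Gaussian
#' smoothing, cycle metric, AMPD cycle isolation, and track extraction over
#' the detected segment.
#'
#' @inheritParams extract_tracks
#' @inheritParams isolate_cycles
#' @param window,sigma Smoothing parameters (see [smooth_recording()]).
#' @return A `feature_tracks` object with the `cycle_segment` attached as
#'   attribute `"segment"`.
#' @export
segment_tracks <- function(recording,
                           families = c("SA", "ED", "JCD", "JTA"),
                           active = active_joints(), reference = "SpineMid",
                           window = NULL, sigma = NULL,
                           n_cycles = 1L, min_prominence = 0.2) {
  smoothed <- smooth_recording(recording, window, sigma)
  metric <- cycle_metric(smoothed, smooth = FALSE)
  segment <- isolate_cycles(metric, n_cycles = n_cycles,
                            min_prominence = min_prominence)
  tracks <- extract_tracks(smoothed, segment, families = families,
                           active = active, reference = reference)
  attr(tracks, "segment") <- segment
  tracks
}

#' Extract feature tracks for a whole cohort
#'
#' Runs [segment_tracks()] on every subject/exercise recording. Exercises
#' recorded in several repetitions (gait) are tried in repetition order and
#' the first with a successful cycle detection is used. Recordings that
#' fail cycle detection are skipped with a logged reason, not an error.
#'
#' @param recordings A tibble with columns `subject_id`, `exercise`,
#'   `repetition`, `recording` (list of `exercise_recording`), e.g. from
#'   [generate_cohort()] or [read_cohort()].
#' @inheritParams segment_tracks
#' @return A `track_set`: tibble with columns `subject_id`, `exercise`,
#'   `tracks` (list of `feature_tracks`); skipped recordings are recorded
#'   in attribute `"log"`.
#' @export
extract_track_sets <- function(recordings,
                               families = c("SA", "ED", "JCD", "JTA"),
                               active = active_joints(),
                               reference = "SpineMid",
                               window = NULL, sigma = NULL,
                               n_cycles = 1L, min_prominence = 0.2) {
  keys <- dplyr::distinct(recordings[, c("subject_id", "exercise")])
  log <- list(); out <- list()
  for (i in seq_len(nrow(keys))) {
    sid <- keys$subject_id[i]; ex <- keys$exercise[i]
    reps <- recordings[recordings$subject_id == sid &
                       recordings$exercise == ex, ]
    reps <- reps[order(reps$repetition), ]
    got <- NULL
    for (r in seq_len(nrow(reps))) {
      got <- tryCatch(
        segment_tracks(reps$recording[[r]], families = families,
                       active = active, reference = reference,
                       window = window, sigma = sigma,
                       n_cycles = n_cycles,
                       min_prominence = min_prominence),
        frailmotion_cycle_error = function(e) {
          log[[length(log) + 1]] <<- tibble::tibble(
            subject_id = sid, exercise = ex,
            repetition = reps$repetition[r],
            reason = conditionMessage(e))
          NULL
        })
      if (!is.null(got)) break
    }
    if (!is.null(got)) out[[length(out) + 1]] <- tibble::tibble(
      subject_id = sid, exercise = ex, tracks = list(got))
  }
  res <- dplyr::bind_rows(out)
  structure(res,
            class = c("track_set", class(res)),
            log = if (length(log)) dplyr::bind_rows(log) else
              tibble::tibble(subject_id = character(0),
                             exercise = character(0),
                             repetition = integer(0), reason = character(0)),
            families = families)
}

#' Aggregate one subject's tracks into a named feature vector
#'
#' Applies the per-family aggregator to every track and concatenates the
#' results. Feature names follow
#' `family:joints[:angle]:bNN` (prefixed `exercise|` in multi-exercise
#' tables); their order is deterministic.
#'
#' @param tracks A `feature_tracks` object.
#' @param aggregation Named vector mapping family to `"resample"` or
#'   `"histogram"` (or a single value for all families).
#' @param nb Number of aggregation bins per track.
#' @param hist_ranges Named list `track name -> c(lo, hi)` of predefined
#'   histogram ranges; tracks without an entry use their own range
#'   (degenerate ranges fall back to `lo - 0.5, hi + 0.5`).
#' @return Named numeric vector of length `nb * n_tracks`.
#' @export
build_feature_vector <- function(tracks, aggregation = default_aggregation(),
                                 nb = 20, hist_ranges = NULL) {
  if (!inherits(tracks, "feature_tracks") || ncol(tracks$matrix) == 0) {
    abort("`tracks` must be a non-empty feature_tracks object",
          class = "frailmotion_validation_error")
  }
  agg <- resolve_aggregation(aggregation, unique(tracks$family))
  nt <- ncol(tracks$matrix)
  out <- matrix(NA_real_, nb, nt)
  nms <- colnames(tracks$matrix)
  for (j in seq_len(nt)) {
    v <- tracks$matrix[, j]
    if (agg[[tracks$family[j]]] == "resample") {
      out[, j] <- aggregate_resample(v, nb)
    } else {
      r <- hist_ranges[[nms[j]]] %||% range(v)
      if (r[1] >= r[2]) r <- c(r[1] - 0.5, r[2] + 0.5)
      out[, j] <- aggregate_histogram(v, nb, r)
    }
  }
  names_out <- paste0(rep(nms, each = nb), ":b",
                      sprintf("%02d", rep(seq_len(nb), nt)))
  setNames(as.vector(out), names_out)
}

resolve_aggregation <- function(aggregation, families) {
  if (is.null(names(aggregation))) {
    if (length(aggregation) != 1) {
      abort("`aggregation` must be a single value or named by family",
            class = "frailmotion_validation_error")
    }
    aggregation <- setNames(rep(aggregation, length(families)), families)
  }
  bad <- setdiff(families, names(aggregation))
  if (length(bad) > 0) {
    abort(paste0("No aggregation given for family: ",
                 paste(bad, collapse = ", ")),
          class = "frailmotion_validation_error")
  }
  ok <- aggregation %in% c("resample", "histogram")
  if (!all(ok)) {
    abort("Aggregation must be \"resample\" or \"histogram\"",
          class = "frailmotion_validation_error")
  }
  as.list(aggregation)
}

#' Build the subjects-by-features table from a track set
#'
#' Aggregates every subject's tracks ([build_feature_vector()]) and binds
#' them into one rectangular table, one row per subject, concatenating
#' exercises with an `exercise|` name prefix when more than one is present.
#' Only subjects with a successful extraction for every requested exercise
#' are kept.
#'
#' Histogram ranges are "predefined" in the sense of being fitted once and
#' frozen: per track, the range is the min/max of that track's values over
#' the subjects selected by `fit_subjects` (all subjects by default; pass
#' the training subjects to keep held-out rows out of the fit). The fitted
#' ranges are attached as attribute `"hist_ranges"`.
#'
#' @param track_set A `track_set` from [extract_track_sets()].
#' @param exercises Exercises to include (default: all present).
#' @param aggregation,nb See [build_feature_vector()].
#' @param fit_subjects Subject ids used to fit histogram ranges; `NULL`
#'   uses all subjects in the set.
#' @param hist_ranges Optional pre-fitted ranges (as attached to a
#'   previously built table), overriding `fit_subjects`.
#' @return A tibble: `subject_id` plus one numeric column per feature,
#'   with attributes `nb`, `aggregation`, `hist_ranges`.
#' @export
build_feature_table <- function(track_set, exercises = NULL,
                                aggregation = default_aggregation(), nb = 20,
                                fit_subjects = NULL, hist_ranges = NULL) {
  exercises <- exercises %||% unique(track_set$exercise)
  ts <- track_set[track_set$exercise %in% exercises, ]
  per_ex <- table(ts$subject_id)
  complete <- names(per_ex)[per_ex == length(exercises)]
  ts <- ts[ts$subject_id %in% complete, ]
  if (nrow(ts) == 0) {
    abort("No subject has a successful extraction for every requested exercise",
          class = "frailmotion_validation_error")
  }

  if (is.null(hist_ranges)) {
    hist_ranges <- fit_hist_ranges(ts, aggregation,
                                   fit_subjects %||% complete)
  }

  multi <- length(exercises) > 1
  rows <- lapply(complete, function(sid) {
    parts <- lapply(exercises, function(ex) {
      tr <- ts$tracks[ts$subject_id == sid & ts$exercise == ex][[1]]
      v <- build_feature_vector(tr, aggregation, nb,
                                hist_ranges = hist_ranges[[ex]])
      if (multi) names(v) <- paste0(ex, "|", names(v))
      v
    })
    unlist(parts)
  })
  mat <- do.call(rbind, rows)
  out <- tibble::as_tibble(as.data.frame(mat, check.names = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(subject_id = complete), out)
  attr(out, "nb") <- nb
  attr(out, "aggregation") <- aggregation
  attr(out, "hist_ranges") <- hist_ranges
  out
}

# Per-exercise, per-track min/max over the fitting subjects.
fit_hist_ranges <- function(ts, aggregation, fit_subjects) {
  out <- list()
  for (ex in unique(ts$exercise)) {
    sub <- ts[ts$exercise == ex & ts$subject_id %in% fit_subjects, ]
    if (nrow(sub) == 0) sub <- ts[ts$exercise == ex, ]
    agg <- resolve_aggregation(aggregation, unique(sub$tracks[[1]]$family))
    hist_fams <- names(agg)[unlist(agg) == "histogram"]
    cols <- which(sub$tracks[[1]]$family %in% hist_fams)
    if (length(cols) == 0) { out[[ex]] <- list(); next }
    lo <- rep(Inf, length(cols)); hi <- rep(-Inf, length(cols))
    for (i in seq_len(nrow(sub))) {
      m <- sub$tracks[[i]]$matrix[, cols, drop = FALSE]
      lo <- pmin(lo, apply(m, 2, min))
      hi <- pmax(hi, apply(m, 2, max))
    }
    rng <- lapply(seq_along(cols), function(k) c(lo[k], hi[k]))
    names(rng) <- colnames(sub$tracks[[1]]$matrix)[cols]
    out[[ex]] <- rng
  }
  out
}
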