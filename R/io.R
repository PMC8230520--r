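#' Read an exercise recording from disk
#'
#' Two dialects are supported. `csv_long` has a header
#' `timestamp,joint,x,y,z`, one row per joint per frame, preceded by
#' `# key: value` comment lines carrying the metadata
#' (`subject_id`, `exercise`, `dominant_hand`, `repetition`, `units`).
#' `json` is an object
#' `{subject_id, exercise, dominant_hand, repetition, units,
#'  frames: [{t, joints: {Name: [x, y, z], ...}}, ...]}`.
#' Coordinates are converted to meters when the file declares
#' `units: mm`.
#'
#' Frames missing one or more joints are repaired at load time: gaps of at
#' most `max_gap` consecutive frames are filled by linear interpolation in
#' time from the neighbouring frames; longer gaps and gaps touching the
#' recording edge cause the affected frames to be dropped. The counts are
#' attached as a load report (see [load_report()]).
#'
#' @param path File to read.
#' @param dialect `"csv_long"` or `"json"`.
#' @param max_gap Longest joint dropout (in frames) repaired by
#'   interpolation; longer gaps drop the frames.
#' @param subject_id,exercise,dominant_hand,repetition Override or supply
#'   metadata not present in the file.
#' @return An [as_recording()] object with a load report attribute.
#' @export
read_recording <- function(path, dialect = c("csv_long", "json"),
                           max_gap = 3L,
                           subject_id = NULL, exercise = NULL,
                           dominant_hand = NULL, repetition = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("No such file: ", path), class = "frailmotion_io_error")
  }
  parsed <- switch(dialect,
                   csv_long = read_dialect_csv(path),
                   json = read_dialect_json(path))
  meta <- parsed$meta
  df <- parsed$data

  if (identical(meta$units %||% "m", "mm")) {
    df$x <- df$x / 1000; df$y <- df$y / 1000; df$z <- df$z / 1000
  }
  unknown <- setdiff(unique(df$joint), kinect_joints())
  if (length(unknown) > 0) {
    abort(paste0("Unknown joint name(s) in file: ",
                 paste(unknown, collapse = ", ")),
          class = "frailmotion_format_error")
  }
  absent <- setdiff(kinect_joints(), unique(df$joint))
  if (length(absent) > 0) {
    abort(paste0("File does not contain the full 25-joint skeleton; missing: ",
                 paste(absent, collapse = ", ")),
          class = "frailmotion_format_error")
  }

  repaired <- repair_missing_joints(df, max_gap = max_gap)
  if (length(unique(repaired$data$time)) < 2) {
    abort("Fewer than 2 usable frames after dropping incomplete frames",
          class = "frailmotion_empty_recording_error")
  }

  rec <- as_recording(
    repaired$data,
    subject_id = subject_id %||% meta$subject_id %||% "unknown",
    exercise = exercise %||% meta$exercise %||% "gait",
    dominant_hand = dominant_hand %||% meta$dominant_hand,
    repetition = repetition %||% meta$repetition %||% 1L
  )
  attr(rec, "load_report") <- tibble::tibble(
    n_frames = n_frames(rec),
    n_imputed = repaired$n_imputed,
    n_dropped = repaired$n_dropped
  )
  rec
}

read_dialect_csv <- function(path) {
  lines <- readLines(path, n = 64L, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*?)\\s*$", ml))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  if (!is.null(meta$repetition)) meta$repetition <- as.integer(meta$repetition)
  df <- tryCatch(
    readr::read_csv(path, comment = "#", show_col_types = FALSE,
                    progress = FALSE),
    error = function(e) abort(paste0("Not a readable csv_long file: ",
                                     conditionMessage(e)),
                              class = "frailmotion_format_error")
  )
  need <- c("timestamp", "joint", "x", "y", "z")
  bad <- setdiff(need, names(df))
  if (length(bad) > 0) {
    abort(paste0("csv_long header must contain `timestamp,joint,x,y,z`; missing: ",
                 paste(bad, collapse = ", ")),
          class = "frailmotion_format_error")
  }
  if (!is.numeric(df$x) || !is.numeric(df$y) || !is.numeric(df$z) ||
      !is.numeric(df$timestamp)) {
    abort("Columns timestamp, x, y, z must be numeric",
          class = "frailmotion_format_error")
  }
  list(meta = meta,
       data = tibble::tibble(time = df$timestamp, joint = df$joint,
                             x = df$x, y = df$y, z = df$z))
}

read_dialect_json <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    abort(paste0("Not a readable json recording: ",
                                 conditionMessage(e)),
                          class = "frailmotion_format_error"))
  if (is.null(obj$frames)) {
    abort("json recording must contain a `frames` array",
          class = "frailmotion_format_error")
  }
  frames <- obj$frames
  # simplifyVector gives a data frame with t and a nested joints data frame
  t <- frames$t
  joints_df <- frames$joints
  if (is.null(t) || is.null(joints_df)) {
    abort("Each frame needs `t` and `joints`", class = "frailmotion_format_error")
  }
  jnames <- names(joints_df)
  rows <- lapply(jnames, function(jn) {
    xyz <- joints_df[[jn]]
    # list column: one [x,y,z] (or NULL) per frame
    mat <- t(vapply(xyz, function(v) {
      if (is.null(v) || length(v) != 3) rep(NA_real_, 3) else as.numeric(v)
    }, numeric(3)))
    tibble::tibble(time = t, joint = jn,
                   x = mat[, 1], y = mat[, 2], z = mat[, 3])
  })
  df <- dplyr::bind_rows(rows)
  df <- df[!(is.na(df$x) & is.na(df$y) & is.na(df$z)), ]
  meta <- obj[intersect(names(obj),
                        c("subject_id", "exercise", "dominant_hand",
                          "repetition", "units"))]
  if (!is.null(meta$repetition)) meta$repetition <- as.integer(meta$repetition)
  list(meta = meta, data = df)
}

# Fill joint dropouts <= max_gap frames by linear interpolation in time;
# drop frames belonging to longer or edge-touching gaps.
repair_missing_joints <- function(df, max_gap = 3L) {
  times <- sort(unique(df$time))
  nf <- length(times)
  joints <- kinect_joints()
  present <- matrix(FALSE, nf, 25L, dimnames = list(NULL, joints))
  fi <- match(df$time, times)
  ji <- match(df$joint, joints)
  present[cbind(fi, ji)] <- TRUE

  coords <- array(NA_real_, c(nf, 25L, 3L))
  coords[cbind(fi, ji, 1L)] <- df$x
  coords[cbind(fi, ji, 2L)] <- df$y
  coords[cbind(fi, ji, 3L)] <- df$z

  drop <- rep(FALSE, nf)
  imputed <- rep(FALSE, nf)
  for (j in seq_len(25L)) {
    miss <- !present[, j]
    if (!any(miss)) next
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (g in which(r$values)) {
      s <- starts[g]; e <- ends[g]
      interior <- s > 1L && e < nf
      if (interior && r$lengths[g] <= max_gap) {
        for (ax in 1:3) {
          coords[s:e, j, ax] <- stats::approx(
            x = times[c(s - 1L, e + 1L)],
            y = coords[c(s - 1L, e + 1L), j, ax],
            xout = times[s:e])$y
        }
        imputed[s:e] <- TRUE
      } else {
        drop[s:e] <- TRUE
      }
    }
  }
  keep <- !drop
  out <- tibble::tibble(
    time = rep(times[keep], each = 25L),
    joint = rep(joints, sum(keep)),
    x = as.vector(t(coords[keep, , 1L, drop = FALSE][, , 1])),
    y = as.vector(t(coords[keep, , 2L, drop = FALSE][, , 1])),
    z = as.vector(t(coords[keep, , 3L, drop = FALSE][, , 1]))
  )
  list(data = out, n_imputed = sum(imputed & keep), n_dropped = sum(drop))
}

#' Write an exercise recording to disk
#'
#' Inverse of [read_recording()]: `read_recording(write_recording(r))`
#' reproduces `r` to numeric tolerance 1e-9 in both dialects.
#'
#' @param recording An `exercise_recording`.
#' @param path Output file.
#' @param dialect `"csv_long"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, dialect = c("csv_long", "json")) {
  dialect <- match.arg(dialect)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort(paste0("Directory does not exist: ", dir),
          class = "frailmotion_io_error")
  }
  meta <- list(subject_id = attr(recording, "subject_id"),
               exercise = attr(recording, "exercise"),
               dominant_hand = attr(recording, "dominant_hand"),
               repetition = attr(recording, "repetition"),
               units = "m")
  meta <- meta[!vapply(meta, is.null, logical(1))]
  if (dialect == "csv_long") {
    hdr <- vapply(names(meta), function(k) sprintf("# %s: %s", k, meta[[k]]),
                  character(1))
    body <- sprintf("%.12g,%s,%.12g,%.12g,%.12g",
                    recording$time, recording$joint,
                    recording$x, recording$y, recording$z)
    writeLines(c(hdr, "timestamp,joint,x,y,z", body), path)
  } else {
    arr <- recording_array(recording)
    frames <- lapply(seq_along(arr$timestamps), function(i) {
      joints <- lapply(seq_len(25L), function(j) unname(arr$coords[i, j, ]))
      names(joints) <- kinect_joints()
      list(t = arr$timestamps[i], joints = joints)
    })
    jsonlite::write_json(c(meta, list(frames = frames)), path,
                         auto_unbox = TRUE, digits = I(12))
  }
  invisible(path)
}
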