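#' Extract the four geometric feature families from a recording
#'
#' Over the frames of a cycle segment, computes per-frame tracks for the
#' requested families:
#' \describe{
#'   \item{SA}{spherical angles (phi, theta) of the 8 limb segments in
#'     [limb_segments()] — 16 tracks;}
#'   \item{ED}{Euclidean distance of every pair of active joints —
#'     `Na (Na - 1) / 2` tracks (210 for the default `Na = 21`);}
#'   \item{JCD}{cosine dissimilarity of every pair of active joints
#'     relative to the spine reference — `(Na - 1)(Na - 2) / 2` tracks
#'     (190);}
#'   \item{JTA}{triangular area of the same triples — 190 tracks.}
#' }
#' Enumeration order is deterministic: families in the order given, limb
#' segments in table order (phi before theta), joint pairs in the fixed
#' order of [kinect_joints()]. Feature names are part of the package
#' contract.
#'
#' The recording should already be smoothed (the pipeline smooths once,
#' before cycle detection, and reuses the smoothed sequence here).
#'
#' @param recording An `exercise_recording`.
#' @param segment A `cycle_segment` from [isolate_cycles()], or `NULL` for
#'   all frames.
#' @param families Subset of `c("SA", "ED", "JCD", "JTA")`.
#' @param active Ordered character vector of active joints (default the
#'   21-joint set of [active_joints()]).
#' @param reference Reference joint for JCD/JTA; the mid-spine by default
#'   (`"SpineBase"` is the supported alternative).
#' @return A `feature_tracks` object: list with `matrix` (frames x tracks,
#'   named columns), `family` (per-column family), `subject_id`,
#'   `exercise`. Use [tracks_table()] for a tidy view.
#' @export
extract_tracks <- function(recording, segment = NULL,
                           families = c("SA", "ED", "JCD", "JTA"),
                           active = active_joints(),
                           reference = "SpineMid") {
  families <- match.arg(families, several.ok = TRUE)
  assert_joint(reference)
  bad <- setdiff(active, kinect_joints())
  if (length(bad) > 0) {
    abort(paste0("Unknown active joint(s): ", paste(bad, collapse = ", ")),
          class = "frailmotion_key_error")
  }
  arr <- recording_array(recording)
  nf <- dim(arr$coords)[1]
  if (is.null(segment)) {
    frames <- seq_len(nf)
  } else {
    if (segment$start < 1 || segment$end > nf + 1 ||
        segment$start >= segment$end) {
      abort(sprintf("Segment [%d, %d) out of range for %d frames",
                    segment$start, segment$end, nf),
            class = "frailmotion_bounds_error")
    }
    frames <- segment_frames(segment)
  }

  X <- arr$coords[frames, , 1L, drop = FALSE][, , 1]
  Y <- arr$coords[frames, , 2L, drop = FALSE][, , 1]
  Z <- arr$coords[frames, , 3L, drop = FALSE][, , 1]
  colnames(X) <- colnames(Y) <- colnames(Z) <- kinect_joints()

  mats <- list(); fams <- character(0)
  for (fam in families) {
    m <- switch(fam,
      SA = tracks_sa(X, Y, Z),
      ED = tracks_ed(X, Y, Z, active),
      JCD = tracks_jcd_jta(X, Y, Z, active, reference, what = "JCD"),
      JTA = tracks_jcd_jta(X, Y, Z, active, reference, what = "JTA"))
    mats[[fam]] <- m
    fams <- c(fams, rep(fam, ncol(m)))
  }
  structure(
    list(matrix = do.call(cbind, mats), family = fams,
         subject_id = attr(recording, "subject_id"),
         exercise = attr(recording, "exercise")),
    class = "feature_tracks"
  )
}

tracks_sa <- function(X, Y, Z) {
  seg <- limb_segments()
  out <- matrix(NA_real_, nrow(X), 2L * nrow(seg))
  nms <- character(2L * nrow(seg))
  for (i in seq_len(nrow(seg))) {
    a <- seg$from[i]; b <- seg$to[i]
    ang <- spherical_angles(cbind(X[, a], Y[, a], Z[, a]),
                            cbind(X[, b], Y[, b], Z[, b]))
    out[, 2 * i - 1] <- ang$phi
    out[, 2 * i] <- ang$theta
    nms[2 * i - 1] <- paste0("SA:", seg$segment[i], ":phi")
    nms[2 * i] <- paste0("SA:", seg$segment[i], ":theta")
  }
  colnames(out) <- nms
  out
}

joint_pairs <- function(joints) {
  n <- length(joints)
  ia <- rep(seq_len(n - 1), times = (n - 1):1)
  ib <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  list(a = joints[ia], b = joints[ib])
}

tracks_ed <- function(X, Y, Z, active) {
  p <- joint_pairs(active)
  out <- sqrt((X[, p$a] - X[, p$b])^2 +
              (Y[, p$a] - Y[, p$b])^2 +
              (Z[, p$a] - Z[, p$b])^2)
  colnames(out) <- paste0("ED:", p$a, "-", p$b)
  out
}

tracks_jcd_jta <- function(X, Y, Z, active, reference, what) {
  joints <- setdiff(active, reference)
  Xr <- X[, joints] - X[, reference]
  Yr <- Y[, joints] - Y[, reference]
  Zr <- Z[, joints] - Z[, reference]
  p <- joint_pairs(joints)
  if (what == "JCD") {
    dot <- Xr[, p$a] * Xr[, p$b] + Yr[, p$a] * Yr[, p$b] + Zr[, p$a] * Zr[, p$b]
    nrm <- sqrt(Xr^2 + Yr^2 + Zr^2)
    out <- 1 - dot / (nrm[, p$a] * nrm[, p$b])
    out[out < 0] <- 0
    out[out > 2] <- 2
  } else {
    cx <- Yr[, p$a] * Zr[, p$b] - Zr[, p$a] * Yr[, p$b]
    cy <- Zr[, p$a] * Xr[, p$b] - Xr[, p$a] * Zr[, p$b]
    cz <- Xr[, p$a] * Yr[, p$b] - Yr[, p$a] * Xr[, p$b]
    out <- sqrt(cx^2 + cy^2 + cz^2) / 2
  }
  colnames(out) <- paste0(what, ":", p$a, "-", p$b)
  out
}

#' @export
print.feature_tracks <- function(x, ...) {
  cat(sprintf("<feature_tracks> subject %s, %s: %d tracks x %d frames (%s)\n",
              x$subject_id, x$exercise, ncol(x$matrix), nrow(x$matrix),
              paste(names(table(x$family)), table(x$family),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Tidy view of extracted feature tracks
#' @param tracks A `feature_tracks` object.
#' @return A tibble with columns `family`, `feature`, `values` (list of
#'   numeric series over the segment).
#' @export
tracks_table <- function(tracks) {
  tibble::tibble(
    family = tracks$family,
    feature = colnames(tracks$matrix),
    values = lapply(seq_len(ncol(tracks$matrix)),
                    function(j) tracks$matrix[, j])
  )
}
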