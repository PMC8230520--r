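#' The 25-joint depth-camera skeleton
#'
#' `kinect_joints()` returns the names of the 25 joints tracked by the Kinect
#' V2 sensor, in the fixed SDK enumeration order. This order is part of the
#' package contract: pairwise feature names and their position in the feature
#' vector are derived from it and are stable across releases.
#'
#' @return A character vector of length 25.
#' @examples
#' kinect_joints()
#' @export
kinect_joints <- function() {
  c(
    "SpineBase", "SpineMid", "Neck", "Head",
    "ShoulderLeft", "ElbowLeft", "WristLeft", "HandLeft",
    "ShoulderRight", "ElbowRight", "WristRight", "HandRight",
    "HipLeft", "KneeLeft", "AnkleLeft", "FootLeft",
    "HipRight", "KneeRight", "AnkleRight", "FootRight",
    "SpineShoulder",
    "HandTipLeft", "ThumbLeft", "HandTipRight", "ThumbRight"
  )
}

#' Active joints used for pairwise features
#'
#' The hand-tip and thumb joints move almost rigidly with the hand and carry
#' little independent information, so the default active set drops them,
#' leaving 21 joints (`Na = 21`). The ordering follows [kinect_joints()] and
#' is fixed: feature names depend on it.
#'
#' @param exclude Character vector of joint names to drop from the full
#'   25-joint set.
#' @return A character vector (21 names by default).
#' @examples
#' length(active_joints())
#' @export
active_joints <- function(exclude = c("HandTipLeft", "HandTipRight",
                                      "ThumbLeft", "ThumbRight")) {
  all <- kinect_joints()
  bad <- setdiff(exclude, all)
  if (length(bad) > 0) {
    abort(paste0("Unknown joint(s): ", paste(bad, collapse = ", ")),
          class = "frailmotion_key_error")
  }
  setdiff(all, exclude)
}

#' Limb segments used for spherical-angle features
#'
#' The eight skeletal primitives with dominant angular movement: left and
#' right humerus (shoulder to elbow), radius (elbow to wrist), femur (hip to
#' knee) and tibia (knee to ankle). Each contributes two spherical angles
#' (phi, theta), giving the 16 angle tracks of the SA family.
#'
#' @return A tibble with columns `segment`, `from`, `to`.
#' @export
limb_segments <- function() {
  tibble::tribble(
    ~segment,        ~from,           ~to,
    "HumerusLeft",   "ShoulderLeft",  "ElbowLeft",
    "HumerusRight",  "ShoulderRight", "ElbowRight",
    "RadiusLeft",    "ElbowLeft",     "WristLeft",
    "RadiusRight",   "ElbowRight",    "WristRight",
    "FemurLeft",     "HipLeft",       "KneeLeft",
    "FemurRight",    "HipRight",      "KneeRight",
    "TibiaLeft",     "KneeLeft",      "AnkleLeft",
    "TibiaRight",    "KneeRight",     "AnkleRight"
  )
}

#' The four exercises of the functional assessment protocol
#' @return Character vector of the four exercise codes.
#' @export
exercise_types <- function() {
  c("arm_curl", "sit_to_stand", "gait", "two_min_step")
}

assert_joint <- function(joint) {
  if (!is.character(joint) || length(joint) != 1 || !joint %in% kinect_joints()) {
    abort(paste0("Unknown joint: ", paste(joint, collapse = ", ")),
          class = "frailmotion_key_error")
  }
  invisible(joint)
}

assert_exercise <- function(exercise) {
  if (!is.character(exercise) || length(exercise) != 1 ||
      !exercise %in% exercise_types()) {
    abort(paste0("`exercise` must be one of: ",
                 paste(exercise_types(), collapse = ", ")),
          class = "frailmotion_validation_error")
  }
  invisible(exercise)
}
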