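#' Geometric primitives on joint coordinates
#'
#' The four feature families are built from these per-frame geometric
#' quantities. All functions are vectorized: points may be numeric vectors
#' of length 3 or n-by-3 matrices (rows = frames).
#'
#' `spherical_angles()` returns the two spherical-coordinate angles of the
#' segment from `p1` to `p2`: the azimuth
#' `phi = atan2(z2 - z1, x2 - x1)` in `(-pi, pi]` and the inclination from
#' the vertical `theta = acos((y2 - y1) / lr)` in `[0, pi]`, with `lr` the
#' Euclidean segment length. For a vertical segment (`dx = dz = 0`) the
#' azimuth follows the `atan2(0, 0) = 0` convention.
#'
#' @param p1,p2 Points (length-3 vectors or n-by-3 matrices).
#' @return `spherical_angles()`: a tibble with columns `phi`, `theta`
#'   (radians); `euclidean_distance()`: numeric, meters.
#' @examples
#' spherical_angles(c(0, 0, 0), c(1, 0, 0))  # phi 0, theta pi/2
#' euclidean_distance(c(0, 0, 0), c(3, 4, 0))  # 5
#' @name geometry
NULL

as_point_matrix <- function(p) {
  if (is.null(dim(p))) {
    if (length(p) != 3) {
      abort("A point must have 3 coordinates",
            class = "frailmotion_validation_error")
    }
    matrix(p, ncol = 3)
  } else {
    if (ncol(p) != 3) {
      abort("Point matrices must have 3 columns",
            class = "frailmotion_validation_error")
    }
    as.matrix(p)
  }
}

#' @rdname geometry
#' @export
spherical_angles <- function(p1, p2) {
  p1 <- as_point_matrix(p1); p2 <- as_point_matrix(p2)
  d <- p2 - p1
  lr <- sqrt(rowSums(d^2))
  if (any(lr == 0)) {
    abort("Coincident points have no segment direction",
          class = "frailmotion_degenerate_geometry_error")
  }
  tibble::tibble(
    phi = atan2(d[, 3], d[, 1]),
    theta = acos(pmin(1, pmax(-1, d[, 2] / lr)))
  )
}

#' @rdname geometry
#' @export
euclidean_distance <- function(p1, p2) {
  p1 <- as_point_matrix(p1); p2 <- as_point_matrix(p2)
  sqrt(rowSums((p2 - p1)^2))
}

#' Cosine dissimilarity of two joints about a reference
#'
#' With `R1 = p1 - ref` and `R2 = p2 - ref`,
#' `delta_c = 1 - (R1 . R2) / (||R1|| ||R2||)`, in `[0, 2]`: 0 for joints
#' seen in the same direction from the reference, 2 for opposite
#' directions. The spine is used as the reference in the JCD feature family
#' because of its stability during the exercises.
#'
#' @param ref,p1,p2 Points (length-3 vectors or n-by-3 matrices).
#' @return Numeric vector in `[0, 2]`.
#' @examples
#' cosine_dissimilarity(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))  # 1
#' @export
cosine_dissimilarity <- function(ref, p1, p2) {
  ref <- as_point_matrix(ref)
  r1 <- as_point_matrix(p1) - ref
  r2 <- as_point_matrix(p2) - ref
  n1 <- sqrt(rowSums(r1^2)); n2 <- sqrt(rowSums(r2^2))
  if (any(n1 == 0 | n2 == 0)) {
    abort("A joint coincides with the reference point",
          class = "frailmotion_degenerate_geometry_error")
  }
  pmin(2, pmax(0, 1 - rowSums(r1 * r2) / (n1 * n2)))
}

#' Triangular area spanned by two joints and a reference
#'
#' `At = ||R1 x R2|| / 2` with `R1`, `R2` as in
#' [cosine_dissimilarity()]; zero exactly when the three points are
#' collinear. Being an area, it is less sensitive to noise than
#' distance- or angle-based quantities.
#'
#' @param ref,p1,p2 Points (length-3 vectors or n-by-3 matrices).
#' @return Numeric vector, square meters (>= 0).
#' @examples
#' triangular_area(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))  # 0.5
#' @export
triangular_area <- function(ref, p1, p2) {
  ref <- as_point_matrix(ref)
  r1 <- as_point_matrix(p1) - ref
  r2 <- as_point_matrix(p2) - ref
  cx <- r1[, 2] * r2[, 3] - r1[, 3] * r2[, 2]
  cy <- r1[, 3] * r2[, 1] - r1[, 1] * r2[, 3]
  cz <- r1[, 1] * r2[, 2] - r1[, 2] * r2[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}
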