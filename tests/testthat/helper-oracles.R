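# Independent brute-force oracles and small fixture builders.

# scalar, loop-based Euclidean distance
bf_distance <- function(p, q) {
  s <- 0
  for (i in 1:3) s <- s + (q[i] - p[i])^2
  sqrt(s)
}

# cosine dissimilarity via the explicit angle between the two rays
bf_cosine_dissimilarity <- function(ref, p1, p2) {
  a <- p1 - ref; b <- p2 - ref
  cosang <- sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  1 - cosang
}

# triangle area via Heron's formula on the three side lengths
bf_triangle_area <- function(ref, p1, p2) {
  a <- bf_distance(ref, p1); b <- bf_distance(ref, p2)
  c <- bf_distance(p1, p2)
  s <- (a + b + c) / 2
  sqrt(max(0, s * (s - a) * (s - b) * (s - c)))
}

# spherical angles from first principles: project onto the horizontal
# plane for the azimuth, use the vertical component for the inclination
bf_spherical <- function(p1, p2) {
  d <- p2 - p1
  lr <- bf_distance(p1, p2)
  c(phi = atan2(d[3], d[1]), theta = acos(min(1, max(-1, d[2] / lr))))
}

random_point <- function() runif(3, -1, 1)

# random rotation matrix from a QR decomposition
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# constant-pose recording with every joint at the base position except
# the overrides (a named list joint -> c(x, y, z))
constant_recording <- function(n = 20, exercise = "sit_to_stand",
                               overrides = list(), dominant_hand = NULL) {
  joints <- kinect_joints()
  pose <- matrix(rep(c(0.5, 1, 2.5), each = length(joints)),
                 ncol = 3, dimnames = list(joints, NULL))
  pose <- pose + matrix(seq_along(joints) * 1e-3, length(joints), 3)
  for (j in names(overrides)) pose[j, ] <- overrides[[j]]
  df <- tibble::tibble(
    time = rep((0:(n - 1)) / 30, each = length(joints)),
    joint = rep(joints, n),
    x = rep(pose[, 1], n), y = rep(pose[, 2], n), z = rep(pose[, 3], n)
  )
  as_recording(df, subject_id = "fix", exercise = exercise,
               dominant_hand = dominant_hand)
}

# small sit-to-stand cohort shared by learning tests
quick_sts_cohort <- function(n_per_class = 8, seed = 421, ...) {
  generate_cohort(cohort_spec(n_per_class = n_per_class,
                              exercises = "sit_to_stand",
                              seed = seed, ...))
}
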