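# Shared fixtures, built once per test run.

# noiseless default pitch + its pipeline result (used by several files)
noiseless_pitch <- function() {
  if (is.null(.fixture_env$pitch0)) {
    .fixture_env$pitch0 <- generate_pitch_motion(
      profile = pitch_profile(pos_noise_m = 0, ori_noise_deg = 0))
  }
  .fixture_env$pitch0
}

noiseless_pipeline <- function() {
  if (is.null(.fixture_env$pk0)) {
    p <- noiseless_pitch()
    .fixture_env$pk0 <- pitch_kinetics(p$recording, p$landmarks)
  }
  .fixture_env$pk0
}

.fixture_env <- new.env(parent = emptyenv())

# random rotation matrix from a random unit quaternion
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

rot_about <- function(axis, deg)
  compose_angles(c(deg, 0, 0), switch(axis, x = "xyz", y = "yxy", z = "zxy"))

# a static single-frame-repeated recording of one sensor at a given pose
static_recording <- function(n = 60, fs = 144, pos = c(0, 0, 0), quat = c(1, 0, 0, 0),
                             label = "s1") {
  sensors <- setNames(list(list(
    pos = matrix(rep(pos, each = n), n, 3),
    quat = matrix(rep(quat, each = n), n, 4)
  )), label)
  motion_recording(fs, sensors)
}

# anatomical-position landmark set (world coords), n frames, optionally
# transformed by rotation R and offset t; returns list(landmarks, gh)
anatomical_landmarks <- function(n = 10, R = diag(3), t = c(0, 0, 0)) {
  pts <- list(
    suprasternal_notch = c(0.05, 1.40, 0),
    c7 = c(-0.05, 1.40, 0),
    t8 = c(0, 1.26, 0),
    epicondyle_medial = c(0, 1.10, 0.13),
    epicondyle_lateral = c(0, 1.10, 0.21),
    styloid_radial = c(0, 0.90, 0.19),
    styloid_ulnar = c(0, 0.90, 0.15)
  )
  gh <- c(0, 1.36, 0.17)
  tf <- function(p) as.numeric(R %*% p + t)
  lms <- lapply(pts, function(p) matrix(rep(tf(p), each = n), n, 3))
  list(landmarks = lms, gh = matrix(rep(tf(gh), each = n), n, 3))
}
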