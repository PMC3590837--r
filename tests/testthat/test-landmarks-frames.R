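toy_map <- function(off = c(0.1, 0.2, 0.3)) {
  base <- data.frame(
    landmark = required_landmarks(), sensor = "s1",
    ox = 0, oy = 0, oz = 0, stringsAsFactors = FALSE)
  base[base$landmark == "c7", c("ox", "oy", "oz")] <- as.list(off)
  landmark_map(base)
}

test_that("identity pose leaves landmark offsets unchanged; translation adds", {
  rec <- static_recording(n = 5)
  g <- landmarks_to_global(rec, toy_map())
  expect_equal(g$c7[1, ], c(0.1, 0.2, 0.3))
  rec_t <- static_recording(n = 5, pos = c(1, -2, 3))
  g <- landmarks_to_global(rec_t, toy_map())
  expect_equal(g$c7[3, ], c(1.1, -1.8, 3.3))
})

test_that("random poses match the homogeneous-transform oracle", {
  set.seed(11)
  for (i in 1:20) {
    R <- random_rotation()
    p <- rnorm(3)
    rec <- static_recording(n = 2, pos = p, quat = pitchload:::rot_to_quat(R))
    off <- rnorm(3)
    g <- landmarks_to_global(rec, toy_map(off))
    oracle <- as.numeric(rbind(cbind(R, p), c(0, 0, 0, 1)) %*% c(off, 1))[1:3]
    expect_lt(max(abs(g$c7[1, ] - oracle)), 1e-12)
  }
})

test_that("unknown host sensors and missing landmarks are rejected", {
  rec <- static_recording(n = 5, label = "other")
  expect_error(landmarks_to_global(rec, toy_map()), "absent from recording")
  df <- as.data.frame(toy_map())
  expect_error(landmark_map(df[-1, ]), "missing required")
})

test_that("anatomical-position fixture yields identity frames", {
  fx <- anatomical_landmarks()
  fr <- build_segment_frames(fx$landmarks, fx$gh)
  for (seg in c("torso", "humerus", "forearm", "hand"))
    expect_lt(max(abs(fr[[seg]]$R[, , 1] - diag(3))), 1e-9)
  expect_equal(fr$humerus$origin[1, ], fx$gh[1, ])
})

test_that("frame construction is equivariant under rigid motion", {
  set.seed(5)
  R <- random_rotation()
  t <- c(0.3, -0.2, 1.1)
  f0 <- anatomical_landmarks()
  f1 <- anatomical_landmarks(R = R, t = t)
  fr0 <- build_segment_frames(f0$landmarks, f0$gh)
  fr1 <- build_segment_frames(f1$landmarks, f1$gh)
  for (seg in c("torso", "humerus", "forearm", "hand")) {
    expect_lt(max(abs(fr1[[seg]]$R[, , 1] - R %*% fr0[[seg]]$R[, , 1])), 1e-9)
    expect_lt(max(abs(fr1[[seg]]$origin[1, ] -
                        (R %*% fr0[[seg]]$origin[1, ] + t))), 1e-9)
  }
})

test_that("emitted rotations are orthonormal with det +1", {
  p <- noiseless_pitch()
  pk <- noiseless_pipeline()
  ks <- sample(pk$frames$n_frames, 25)
  for (seg in c("torso", "humerus", "forearm", "hand")) {
    for (k in ks) {
      R <- pk$frames[[seg]]$R[, , k]
      expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
      expect_lt(abs(det(R) - 1), 1e-9)
    }
  }
})

test_that("collinear defining points are rejected with the segment name", {
  fx <- anatomical_landmarks()
  bad <- fx$landmarks
  bad$epicondyle_medial <- bad$epicondyle_lateral  # degenerate elbow axis
  expect_error(build_segment_frames(bad, fx$gh), "humerus")
  fx2 <- anatomical_landmarks()
  bad2 <- fx2$landmarks
  bad2$styloid_radial <- bad2$styloid_ulnar
  expect_error(build_segment_frames(bad2, fx2$gh), "forearm")
})
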