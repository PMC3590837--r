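test_that("mirroring twice reproduces the recording bit-for-bit", {
  p <- noiseless_pitch()
  twice <- mirror_world_z(mirror_world_z(p$recording))
  expect_identical(twice, p$recording)
})

test_that("mirrored rotations stay proper rotations", {
  p <- noiseless_pitch()
  m <- mirror_world_z(p$recording)
  q <- m$sensors$humerus_throw$quat[50, ]
  R <- pitchload:::quat_to_rot(q)
  expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
  expect_lt(abs(det(R) - 1), 1e-9)
})

test_that("left-handed twin yields identical peak kinetics", {
  p_r <- noiseless_pitch()
  pk_r <- noiseless_pipeline()
  p_l <- generate_pitch_motion(handedness = "L",
                               profile = pitch_profile(pos_noise_m = 0, ori_noise_deg = 0))
  expect_identical(p_l$recording$handedness, "L")
  pk_l <- pitch_kinetics(p_l$recording, p_l$landmarks)
  expect_lt(abs(pk_l$peaks$paf_n - pk_r$peaks$paf_n), 1e-9)
  expect_lt(abs(pk_l$peaks$ppf_n - pk_r$peaks$ppf_n), 1e-9)
  expect_identical(pk_l$events$mer, pk_r$events$mer)
})

test_that("detected events agree with generator truth within 2 frames", {
  for (s in 1:3) {
    p <- generate_pitch_motion(profile = pitch_profile(seed = s))
    pk <- pitch_kinetics(p$recording, p$landmarks)
    expect_lte(abs(pk$events$sfc - p$truth$events$sfc), 2)
    expect_lte(abs(pk$events$mer - p$truth$events$mer), 2)
    expect_lte(abs(pk$events$br - p$truth$events$br), 2)
  }
})

test_that("monotone axial rotation puts MER on the boundary with a warning", {
  n <- 60
  fs <- 144
  lms <- anatomical_landmarks(n = n)$landmarks
  gh <- anatomical_landmarks(n = n)$gh
  # steadily externally rotating humerus, no extremum inside the trace
  for (k in seq_len(n)) {
    ang <- 80 * (k - 1) / (n - 1)
    R <- compose_angles(c(0, 45, ang), "yxy")
    base <- anatomical_landmarks(n = 1)$landmarks
    rot_pt <- function(p) as.numeric(R %*% (p - gh[1, ]) + gh[1, ])
    lms$epicondyle_medial[k, ] <- rot_pt(base$epicondyle_medial[1, ])
    lms$epicondyle_lateral[k, ] <- rot_pt(base$epicondyle_lateral[1, ])
    lms$styloid_radial[k, ] <- rot_pt(base$styloid_radial[1, ])
    lms$styloid_ulnar[k, ] <- rot_pt(base$styloid_ulnar[1, ])
  }
  fr <- build_segment_frames(lms, gh)
  expect_warning(
    try(detect_events(fr, fs, shank_z = rep(0.02, n), height_cm = 142.6), silent = TRUE),
    "boundary")
})

test_that("a recording truncated before release raises an ordered-events error", {
  p <- noiseless_pitch()
  pk <- noiseless_pipeline()
  cut <- p$truth$events$mer + 1L
  fr <- pk$frames
  for (seg in c("torso", "humerus", "forearm", "hand")) {
    fr[[seg]]$origin <- fr[[seg]]$origin[1:cut, , drop = FALSE]
    fr[[seg]]$R <- fr[[seg]]$R[, , 1:cut, drop = FALSE]
  }
  fr$n_frames <- cut
  shank_z <- p$recording$sensors$shank_lead$pos[1:cut, 3]
  expect_error(
    suppressWarnings(detect_events(fr, p$recording$fs, shank_z = shank_z,
                                   height_cm = 142.6)),
    "out of order|truncated")
})
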