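static_chain <- function(n = 40, ball = 0.145) {
  fx <- anatomical_landmarks(n = n)
  fr <- build_segment_frames(fx$landmarks, fx$gh)
  model <- scale_segment_parameters(142.6, 41.1, ball_mass_kg = ball)
  kin <- segment_com_kinematics(fr, model, fs = 144)
  list(fr = fr, model = model, kin = kin, n = n)
}

test_that("static pose gives shoulder force equal to the hanging weight", {
  st <- static_chain()
  ne <- newton_euler_chain(st$kin, st$model, events = list(br = st$n))
  w <- (sum(st$model$segments$mass_kg) + st$model$ball_mass_kg) * 9.81
  mag <- sqrt(rowSums(ne$shoulder^2))
  expect_lt(max(abs(mag - w)) / w, 1e-9)
  expect_true(all(ne$shoulder[, 3] > 0))  # supporting force points up
})

test_that("ball mass superposes exactly in the static limit", {
  st1 <- static_chain(ball = 0)
  st2 <- static_chain(ball = 0.145)
  ne1 <- newton_euler_chain(st1$kin, st1$model, events = list(br = st1$n))
  ne2 <- newton_euler_chain(st2$kin, st2$model, events = list(br = st2$n))
  dmag <- sqrt(rowSums((ne2$shoulder - ne1$shoulder)^2))
  expect_lt(max(abs(dmag - 0.145 * 9.81)), 1e-12)
})

test_that("recursive chain matches the momentum oracle on noiseless motion", {
  p <- noiseless_pitch()
  kin <- p$truth$kin
  ne <- newton_euler_chain(kin, p$model, events = p$truth$events)
  orc <- momentum_oracle(kin, p$model, br = p$truth$events$br)
  scale <- max(sqrt(rowSums(orc^2)))
  rel <- sqrt(rowSums((ne$shoulder - orc)^2)) / scale
  expect_lt(max(rel), 1e-3)
})

test_that("missing segments and NaN kinematics are rejected", {
  st <- static_chain()
  kin2 <- st$kin
  kin2$forearm <- NULL
  expect_error(momentum_oracle(kin2, st$model), "missing")
  kin3 <- st$kin
  kin3$hand$acc[7, 2] <- NaN
  expect_error(newton_euler_chain(kin3, st$model, events = list(br = st$n)),
               "frame 7")
})

test_that("component resolution projects onto the humerus axes", {
  n <- 4
  Rarr <- array(rep(diag(3), n), c(3, 3, n))
  f_prox <- matrix(rep(c(0, 7, 0), each = n), n, 3)
  expect_equal(unname(resolve_shoulder_components(f_prox, Rarr)[1, ]), c(0, 0, 7))
  f_ant <- matrix(rep(c(7, 0, 0), each = n), n, 3)
  expect_equal(unname(resolve_shoulder_components(f_ant, Rarr)[1, ]), c(7, 0, 0))
})

test_that("component resolution preserves the force norm for random frames", {
  set.seed(9)
  n <- 30
  Rarr <- array(0, c(3, 3, n))
  for (k in 1:n) Rarr[, , k] <- random_rotation()
  f <- matrix(rnorm(3 * n, sd = 50), n, 3)
  comp <- resolve_shoulder_components(f, Rarr)
  expect_lt(max(abs(rowSums(comp^2) - rowSums(f^2))), 1e-9 * max(rowSums(f^2)))
})

test_that("percent-bodyweight normalization and its inverse are exact", {
  expect_equal(normalize_percent_bw(41.1 * 9.81, 41.1), 100)
  expect_equal(normalize_percent_bw(0, 41.1), 0)
  expect_equal(round(normalize_percent_bw(201.59, 41.1), 1), 50.0)
  f <- rnorm(20, sd = 100)
  back <- normalize_percent_bw(f, 63.2) * 63.2 * 9.81 / 100
  expect_lt(max(abs(back - f)), 1e-12 * max(abs(f)))
  expect_error(normalize_percent_bw(10, 0), "positive")
})

test_that("peak extraction finds planted maxima and honours the tie rule", {
  n <- 100
  fs <- 144
  Rarr <- array(rep(diag(3), n), c(3, 3, n))
  f <- matrix(0, n, 3)
  f[, 1] <- dnorm(seq_len(n), 30, 4) * 100   # anterior bump at frame 30
  f[, 2] <- dnorm(seq_len(n), 70, 4) * 300   # proximal bump at frame 70
  ser <- shoulder_kinetics_series(f, Rarr, mass_kg = 41.1, fs = fs)
  ev <- list(sfc = 10L, mer = 50L, br = 90L)
  pk <- extract_peak_kinetics(ser, ev)
  expect_equal(pk$paf_frame, 30L)
  expect_equal(pk$ppf_frame, 70L)
  expect_equal(pk$ppf_pctbw, normalize_percent_bw(pk$ppf_n, 41.1))
  # constant series: tie broken to the window start
  fc <- matrix(5, n, 3)
  serc <- shoulder_kinetics_series(fc, Rarr, 41.1, fs)
  pkc <- extract_peak_kinetics(serc, ev)
  expect_equal(pkc$paf_frame, ev$sfc)
  expect_equal(pkc$ppf_frame, ev$mer)
  # degenerate acceleration window
  expect_error(extract_peak_kinetics(ser, list(sfc = 10L, mer = 70L, br = 70L)),
               "acceleration")
})

test_that("validation summary is zero for perfect estimates and 6.4% for a 1.064 scale", {
  p <- noiseless_pitch()
  n <- length(p$truth$anterior_n)
  Rarr <- p$truth$kin$humerus$R
  ser_true <- shoulder_kinetics_series(p$truth$force_n, Rarr, 41.1, 144)
  v0 <- validate_kinetics(ser_true, p$truth)
  expect_lt(v0$peak_mean_pct, 1e-9)
  ser_scaled <- ser_true
  ser_scaled$anterior_n <- 1.064 * ser_true$anterior_n
  ser_scaled$proximal_n <- 1.064 * ser_true$proximal_n
  v <- validate_kinetics(ser_scaled, p$truth)
  expect_equal(v$paf_pct, 6.4, tolerance = 1e-9)
  expect_equal(v$ppf_pct, 6.4, tolerance = 1e-9)
  bad <- p$truth
  bad$anterior_n <- bad$anterior_n[1:10]
  expect_error(validate_kinetics(ser_true, bad), "mismatch")
})

test_that("peak proximal force bounds the window endpoints", {
  pk <- noiseless_pipeline()
  ev <- pk$events
  expect_gte(pk$peaks$ppf_n, pk$series$proximal_n[ev$mer])
  expect_gte(pk$peaks$ppf_n, pk$series$proximal_n[ev$br])
})

test_that("angular kinematics recover constant spin and vanish when static", {
  n <- 60
  fs <- 144
  omega_true <- 3.2  # rad/s about world z
  Rarr <- array(0, c(3, 3, n))
  for (k in 1:n) Rarr[, , k] <- pitchload:::rotvec_to_rot(c(0, 0, omega_true * (k - 1) / fs))
  ak <- angular_kinematics(Rarr, fs)
  interior <- 2:(n - 1)
  expect_lt(max(abs(ak$omega[interior, 3] - omega_true)), 1e-6)
  expect_lt(max(abs(ak$omega[interior, 1:2])), 1e-6)
  stat <- array(rep(random_rotation(), n), c(3, 3, n))
  aks <- angular_kinematics(stat, fs)
  expect_lt(max(abs(aks$omega)), 1e-12)
  expect_lt(max(abs(aks$alpha)), 1e-12)
})

test_that("angular velocity matches a high-resolution derivative oracle", {
  fs <- 144
  n <- 80
  tv <- (seq_len(n) - 1) / fs
  Rfun <- function(t) compose_angles(c(25 * sin(2 * pi * 0.8 * t),
                                       40 + 20 * cos(2 * pi * 0.6 * t),
                                       30 * sin(2 * pi * 1.0 * t)), "yxy")
  Rarr <- array(0, c(3, 3, n))
  for (k in 1:n) Rarr[, , k] <- Rfun(tv[k])
  ak <- angular_kinematics(Rarr, fs)
  h <- 1e-5
  worst <- 0
  scale <- max(sqrt(rowSums(ak$omega^2)))
  for (k in seq(5, n - 4, by = 5)) {
    w_oracle <- pitchload:::rot_log(Rfun(tv[k] + h) %*% t(Rfun(tv[k] - h))) / (2 * h)
    worst <- max(worst, sqrt(sum((ak$omega[k, ] - w_oracle)^2)) / scale)
  }
  expect_lt(worst, 1e-3)
})
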