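test_that("empty cohort request returns a fully headed empty table", {
  co <- generate_cohort(cohort_params(n = 0))
  expect_s3_class(co, "cohort_table")
  expect_equal(nrow(co), 0L)
  expect_true(all(c("id", "age_y", "height_cm", "mass_kg", "handedness",
                    "paf_n", "ppf_n", "pain") %in% names(co)))
})

test_that("cohort generation is deterministic given the seed", {
  a <- generate_cohort(cohort_params(n = 500, seed = 99))
  b <- generate_cohort(cohort_params(n = 500, seed = 99))
  expect_identical(a, b)
  c <- generate_cohort(cohort_params(n = 500, seed = 100))
  expect_false(identical(a$ppf_n, c$ppf_n))
})

test_that("cohort moments converge to the generating parameters", {
  prm <- cohort_params(n = 20000, seed = 4)
  co <- generate_cohort(prm)
  se_mean <- prm$ppf_sd / sqrt(prm$n)
  expect_lt(abs(mean(co$ppf_n) - prm$ppf_mean), 3 * se_mean)
  expect_lt(abs(sd(co$ppf_n) - prm$ppf_sd), 3 * prm$ppf_sd / sqrt(2 * prm$n))
  expect_lt(abs(mean(co$paf_n) - prm$paf_mean), 3 * prm$paf_sd / sqrt(prm$n))
})

test_that("a zero-slope cohort shows no exposure effect", {
  prm <- cohort_params(n = 20000, slope = 0, intercept = -0.5, seed = 8)
  co <- generate_cohort(prm)
  prev <- mean(co$pain)
  expect_lt(abs(prev - plogis(-0.5)), 0.01)
  fit <- fit_logistic(co$ppf_n, co$pain)
  expect_lt(abs(fit$coefficients["slope"]), 3 * fit$se["slope"])
})

test_that("requested PAF-PPF correlation is realized", {
  co <- generate_cohort(cohort_params(n = 20000, paf_ppf_cor = 0.6, seed = 5))
  expect_lt(abs(cor(co$paf_n, co$ppf_n) - 0.6), 0.02)
  co0 <- generate_cohort(cohort_params(n = 20000, seed = 5))
  expect_lt(abs(cor(co0$paf_n, co0$ppf_n)), 0.025)
})

test_that("invalid cohort parameters are rejected", {
  expect_error(cohort_params(n = -1), "n must be")
  expect_error(cohort_params(ppf_sd = 0), "SDs")
  expect_error(cohort_params(paf_ppf_cor = 1.5), "cor")
  expect_error(cohort_params(slope = Inf), "finite")
})

test_that("a static pose yields the constant hanging weight as ground truth", {
  flat <- function(v) rep(v, 5)
  prof <- pitch_profile(
    channels = list(stride_frac = flat(0.1), yaw = flat(-20), plane = flat(10),
                    elevation = flat(60), axial = flat(30), elbow = flat(45),
                    shank_h_frac = flat(0.05), shank_x_frac = flat(0.2)),
    pos_noise_m = 0, ori_noise_deg = 0)
  p <- generate_pitch_motion(profile = prof)
  w <- (sum(p$model$segments$mass_kg) + p$model$ball_mass_kg) * 9.81
  mag <- sqrt(rowSums(p$truth$force_n^2))
  br <- p$truth$events$br
  expect_lt(max(abs(mag[1:br] - w)) / w, 1e-6)
  spread <- apply(p$truth$force_n[1:br, ], 2, function(col) diff(range(col)))
  expect_lt(max(spread), 1e-4)
})

test_that("pitch generation is deterministic and frame counts follow the profile", {
  pr <- pitch_profile(seed = 21)
  a <- generate_pitch_motion(profile = pr)
  b <- generate_pitch_motion(profile = pr)
  expect_identical(a$recording, b$recording)
  expect_equal(n_frames <- nrow(a$recording$sensors$torso$pos),
               floor(sum(pr$phase_s) * pr$fs) + 1)
  expect_length(a$recording$sensors, 10L)
})

test_that("profiles violating the invariants are rejected", {
  expect_error(pitch_profile(phase_s = c(windup = 0, cocking = 0.3,
                                         acceleration = 0.3, follow = 0.3)),
               "positive")
  expect_error(pitch_profile(pos_noise_m = -1), ">= 0")
  expect_error(pitch_profile(phase_s = c(windup = 0.01, cocking = 0.01,
                                         acceleration = 0.01, follow = 0.01)),
               "16")
  expect_error(generate_pitch_motion(height_cm = -1), "positive")
})

test_that("ground-truth events are ordered and the force series finite", {
  p <- noiseless_pitch()
  ev <- p$truth$events
  expect_true(ev$sfc < ev$mer && ev$mer < ev$br)
  expect_true(all(is.finite(p$truth$force_n)))
})
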