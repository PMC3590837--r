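# pivot-fit fixture: humerus sensor rotating about a known fixed point,
# expressed directly in a static torso frame
pivot_fixture <- function(n = 120, center = c(0.1, -0.05, 0.2),
                          p_local = c(0.05, -0.25, 0.04),
                          noise = 0, seed = 1,
                          axes = list(c(0, 0, 1), c(1, 0, 0))) {
  set.seed(seed)
  hp <- matrix(0, n, 3); hq <- matrix(0, n, 4)
  for (k in seq_len(n)) {
    ax <- axes[[(k %% length(axes)) + 1L]]
    ang <- 0.8 * sin(2 * pi * k / n) + 0.3 * cos(4 * pi * k / n)
    R <- pitchload:::rotvec_to_rot(ax * ang)
    hp[k, ] <- center - R %*% p_local + rnorm(3, sd = noise)
    hq[k, ] <- pitchload:::rot_to_quat(R)
  }
  tp <- matrix(0, n, 3)
  tq <- matrix(rep(c(1, 0, 0, 0), each = n), n, 4)
  list(hp = hp, hq = hq, tp = tp, tq = tq, center = center, p_local = p_local)
}

test_that("noiseless rotation about a fixed point recovers it exactly", {
  fx <- pivot_fixture()
  fit <- estimate_gh_center(fx$hp, fx$hq, fx$tp, fx$tq)
  expect_lt(max(abs(fit$center_torso - fx$center)), 1e-6)
  expect_lt(max(abs(fit$center_humerus - fx$p_local)), 1e-6)
  expect_lt(fit$rms_m, 1e-9)
  expect_false(fit$ill_conditioned)
})

test_that("2 mm noise over 200 two-axis frames recovers the pivot within 5 mm (95th pct)", {
  errs <- vapply(1:100, function(s) {
    fx <- pivot_fixture(n = 200, noise = 0.002, seed = s)
    fit <- estimate_gh_center(fx$hp, fx$hq, fx$tp, fx$tq)
    sqrt(sum((fit$center_torso - fx$center)^2))
  }, numeric(1))
  expect_lt(unname(quantile(errs, 0.95)), 0.005)
})

test_that("pure translation is flagged ill-conditioned", {
  n <- 80
  hp <- cbind(seq(0, 0.5, length.out = n), 0, 0)
  hq <- matrix(rep(c(1, 0, 0, 0), each = n), n, 4)
  tp <- matrix(0, n, 3)
  tq <- hq
  expect_warning(fit <- estimate_gh_center(hp, hq, tp, tq), "ill-conditioned")
  expect_true(fit$ill_conditioned)
})

test_that("too few frames are rejected", {
  fx <- pivot_fixture(n = 30)
  expect_error(estimate_gh_center(fx$hp, fx$hq, fx$tp, fx$tq), "50 frames")
})
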