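# Oracles: analytic Butterworth magnitude response, minimum-jerk closed
# forms, and hand-traced threshold rules.

test_that("zero-phase filter preserves DC and matches the analytic transfer function", {
  expect_equal(lowpass_filter(rep(44, 100)), rep(44, 100), tolerance = 1e-9)

  t <- seq(0, 5, by = 0.01)
  ctr <- 150:350  # central half, away from edge transients
  # dual-pass 2nd-order Butterworth amplitude: 1 / (1 + (f/fc)^4)
  dual_gain <- function(f, fc = 6) 1 / (1 + (f / fc)^4)

  f1 <- lowpass_filter(sin(2 * pi * 1 * t))
  expect_lt(abs(max(abs(f1[ctr])) - 1), 0.02)  # 1 Hz passes (analytic 0.9992)

  f20 <- lowpass_filter(sin(2 * pi * 20 * t))
  expect_lt(max(abs(f20[ctr])), dual_gain(20) * 1.02)

  expect_error(lowpass_filter(rep(1, 10)), "at least 27")
})

test_that("derivatives recover constant-velocity motion and are reversal-symmetric", {
  n <- 50
  xyz <- cbind(seq(0, by = 1, length.out = n), 0, 0)  # 100 mm/s at 100 Hz
  d <- kinematic_derivatives(xyz, fs_hz = 100)
  expect_equal(d$speed, rep(100, n), tolerance = 1e-6)
  expect_equal(d$acceleration, rep(0, n), tolerance = 1e-6)

  set.seed(1)
  wob <- cbind(cumsum(rnorm(n)), cumsum(rnorm(n)), cumsum(rnorm(n)))
  fwd <- kinematic_derivatives(wob, 100)$speed
  rev_ <- kinematic_derivatives(wob[n:1, ], 100)$speed
  expect_equal(rev_, rev(fwd), tolerance = 1e-9)

  expect_error(kinematic_derivatives(xyz[1:4, ], 100), "at least 5")
})

test_that("minimum-jerk reach has peak speed 15d/(8T) at mid-movement", {
  # 440 mm reach in 1 s: closed-form peak 825 mm/s at 50% of duration
  tau <- seq(0, 1, length.out = 101)
  pos <- cbind(440 * (10 * tau^3 - 15 * tau^4 + 6 * tau^5), 0, 0)
  d <- kinematic_derivatives(pos, fs_hz = 100)
  expect_equal(max(d$speed), 15 * 440 / 8, tolerance = 0.005)
  expect_equal(which.max(d$speed), 51)  # mid-movement sample
})

test_that("grip aperture is the per-frame Euclidean thumb-index distance", {
  z <- matrix(0, 5, 3)
  expect_equal(grip_aperture(z, z), rep(0, 5))
  off <- matrix(rep(c(3, 4, 0), each = 5), 5, 3)
  expect_equal(grip_aperture(z, off), rep(5, 5))  # 3-4-5 triangle
  ramp <- cbind(0:60, 0, 0)
  expect_equal(grip_aperture(matrix(0, 61, 3), ramp), as.numeric(0:60))
  expect_error(grip_aperture(z, matrix(0, 4, 3)), "identical dimensions")
})

test_that("movement bounds follow the sustained-threshold rule", {
  # hand-traced: above-20 run frames 2..7 (>= 5 frames), below-run from 8
  speed <- c(0, 0, 30, 40, 50, 60, 50, 40, 10, 0, 0, 0, 0, 0)
  b <- detect_bounds(speed, fs_hz = 100)
  expect_identical(b$onset, 2L)
  expect_identical(b$offset, 8L)

  expect_error(detect_bounds(rep(0, 20), 100), "no movement detected")
  expect_error(detect_bounds(rep(100, 20), 100), "no offset")
})

test_that("bound detection ignores brief suprathreshold noise away from the peak", {
  speed <- c(25, 25, rep(0, 10), rep(80, 20), rep(0, 10))
  b <- detect_bounds(speed, fs_hz = 100)
  expect_identical(b$onset, 12L)
  expect_identical(b$offset, 32L)
})

test_that("time normalization interpolates at deciles of duration", {
  expect_equal(time_normalize(0:100, 0, 100), seq(10, 100, by = 10))
  expect_equal(time_normalize(rep(7, 30), 0, 29), rep(7, 10))
  # hand interpolation on [0,1,4,9,16]: fractional indices 0.4, 0.8, ..., 4
  v <- time_normalize(c(0, 1, 4, 9, 16), 0, 4)
  idx <- 0.4 * (1:10)
  lo <- floor(idx); hi <- ceiling(idx)
  sq <- c(0, 1, 4, 9, 16)
  expect_equal(v, sq[lo + 1] + (idx - lo) * (sq[hi + 1] - sq[lo + 1]))
  expect_equal(v[1], 0.4)
  expect_equal(v[10], 16)
  expect_error(time_normalize(1:10, 5, 20), "outside")
})

test_that("profile extraction puts the min-jerk velocity peak at mid-movement", {
  tr <- fx_minjerk_trial()$trial
  pr <- extract_profile(tr)
  expect_length(pr$velocity, 10)
  expect_identical(which.max(pr$velocity), 5L)  # 50% of duration
  expect_equal(max(pr$velocity), 825, tolerance = 0.005)
  expect_true(all(pr$aperture >= 0))
  expect_lt(pr$onset_frame, pr$offset_frame)

  # identical trials give identical 50-vectors
  expect_identical(flatten_profile(pr), flatten_profile(extract_profile(tr)))
})

test_that("raising the hand shifts only the height features", {
  tr <- fx_minjerk_trial()$trial
  tr2 <- tr
  tr2$markers <- lapply(tr$markers, function(m) sweep(m, 2, c(0, 0, 50), `+`))
  f1 <- flatten_profile(extract_profile(tr))
  f2 <- flatten_profile(extract_profile(tr2))
  expect_equal(f2[41:50], f1[41:50] + 50, tolerance = 1e-9)
  expect_equal(f2[1:40], f1[1:40], tolerance = 1e-9)
})

test_that("rotation about the vertical axis leaves all features unchanged", {
  tr <- fx_minjerk_trial()$trial
  th <- pi / 6
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  tr2 <- tr
  tr2$markers <- lapply(tr$markers, function(m) m %*% t(R))
  f1 <- flatten_profile(extract_profile(tr))
  f2 <- flatten_profile(extract_profile(tr2))
  expect_equal(f2, f1, tolerance = 1e-6)
})

test_that("time-rescaling preserves the normalized velocity shape", {
  cfg <- fx_minjerk_trial()$config
  sub <- fx_minjerk_trial()$subject
  slow <- sub
  slow$duration <- sub$duration * 2
  set.seed(1)
  v_fast <- extract_profile(generate_trial(sub[1, ], "place", cfg))$velocity
  v_slow <- extract_profile(generate_trial(slow[1, ], "place", cfg))$velocity
  # shapes agree up to the onset-threshold clipping, which trims a larger
  # fraction of the slower (lower-peak-speed) movement
  expect_lt(max(abs(v_slow / max(v_slow) - v_fast / max(v_fast))), 0.05)
})
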