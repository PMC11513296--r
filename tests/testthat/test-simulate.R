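g <- scan_geometry()

test_that("geometry constants and unit ridge velocity", {
  expect_equal(px_per_sample_velocity(g), 21.7e-6 * 92000)
  expect_error(scan_geometry(lateral_um_per_px = -1), "positive")
})

test_that("phase wrapping conserves value modulo 2*pi", {
  x <- c(-10, -pi, -1, 0, 1, pi, 10, 123.456)
  w <- wrap_phase(x)
  expect_true(all(w >= -pi & w < pi))
  k <- (x - w) / (2 * pi)
  expect_equal(k, round(k))
})

test_that("argmax ridge advances one pixel per sample at the unit velocity", {
  cfg <- sim_config(velocity_mps = px_per_sample_velocity(g), depth_px = 2,
                    lateral_px = 64, time_px = 192, n_pulses = 1,
                    noise_sigma_rad = 0)
  d <- simulate_displacement(cfg, g)
  ridge <- apply(d[1, , ], 1, which.max)
  expect_equal(unique(diff(ridge)), 1L)
})

test_that("brute-force ridge tracking recovers homogeneous velocities within 1%", {
  for (v in c(2, 4, 8, 16)) {
    cfg <- sim_config(velocity_mps = v, depth_px = 1, lateral_px = 256,
                      time_px = 512, n_pulses = 1, noise_sigma_rad = 0)
    d <- simulate_displacement(cfg, g)
    ridge <- apply(d[1, , ], 1, which.max)
    x <- seq_along(ridge)
    slope <- coef(lm(ridge ~ x))[[2]]
    expect_lt(abs(px_per_sample_velocity(g) / slope - v) / v, 0.01)
  }
})

test_that("attenuation-free packets have equal amplitude everywhere", {
  # unit ridge velocity -> integer-sample delays, so the sampled packet is
  # identical at every lateral position
  cfg <- sim_config(velocity_mps = px_per_sample_velocity(g), depth_px = 3,
                    lateral_px = 32, time_px = 256, n_pulses = 1,
                    lateral_attenuation_per_mm = 0,
                    depth_attenuation_per_mm = 0)
  d <- simulate_displacement(cfg, g)
  peaks <- apply(abs(d), c(1, 2), max)
  expect_equal(max(peaks) - min(peaks), 0, tolerance = 1e-10)
})

test_that("piecewise velocity segments are recovered on either side of the boundary", {
  seg <- data.frame(lateral_start_px = c(1, 33), lateral_end_px = c(32, 64),
                    velocity_mps = c(4, 9))
  cfg <- sim_config(velocity_mps = seg, depth_px = 1, lateral_px = 64,
                    time_px = 256, n_pulses = 1,
                    lateral_attenuation_per_mm = 0)
  d <- simulate_displacement(cfg, g)
  ridge <- apply(d[1, , ], 1, which.max)
  fit_v <- function(sel) {
    s <- coef(lm(ridge[sel] ~ sel))[[2]]
    px_per_sample_velocity(g) / s
  }
  v1 <- fit_v(1:32)
  v2 <- fit_v(33:64)
  expect_lt(abs(v1 - 4) / 4, 0.02)
  expect_lt(abs(v2 - 9) / 9, 0.02)
  expect_gt(v2, v1)  # steeper ridge flattens across the boundary
})

test_that("non-positive velocities are rejected naming the segment", {
  expect_error(sim_config(velocity_mps = -2), "velocity must be > 0")
  seg <- data.frame(lateral_start_px = c(1, 17), lateral_end_px = c(16, 32),
                    velocity_mps = c(5, 0))
  expect_error(sim_config(velocity_mps = seg, lateral_px = 32), "segment 2")
  bad <- data.frame(lateral_start_px = c(1, 10), lateral_end_px = c(16, 32),
                    velocity_mps = c(5, 6))
  expect_error(sim_config(velocity_mps = bad, lateral_px = 32), "tile")
})

test_that("raw phase volumes honour the wrapping and determinism contracts", {
  cfg <- sim_config(velocity_mps = 5, depth_px = 4, lateral_px = 24,
                    time_px = 48, seed = 77)
  v1 <- simulate_volume(cfg, g)
  v2 <- simulate_volume(cfg, g)
  expect_identical(v1$phase, v2$phase)      # bit-identical given the seed
  expect_true(all(v1$phase >= -pi & v1$phase <= pi))
  expect_equal(dim(v1$phase), c(4, 24, 48))
  expect_equal(v1$oracle_velocity$per_lateral, rep(5, 24))
})

test_that("zero modulation and zero noise give time-constant phase", {
  cfg <- sim_config(velocity_mps = 5, amplitude_rad = 0,
                    noise_sigma_rad = 0, depth_px = 2, lateral_px = 8,
                    time_px = 16, seed = 1)
  vol <- simulate_volume(cfg, g)
  spread <- apply(vol$phase, c(1, 2), function(ts) diff(range(ts)))
  expect_equal(max(spread), 0)
})

test_that("motion artifacts stay wrapped and reproducible", {
  for (m in c("drift", "jump")) {
    cfg <- sim_config(velocity_mps = 5, depth_px = 2, lateral_px = 8,
                      time_px = 64, motion_artifact = m, seed = 5)
    v1 <- simulate_volume(cfg, g)
    v2 <- simulate_volume(cfg, g)
    expect_identical(v1$phase, v2$phase)
    expect_true(all(v1$phase >= -pi & v1$phase < pi))
  }
})

test_that("displacement_to_phase rejects non-finite input", {
  cfg <- sim_config(depth_px = 1, lateral_px = 4, time_px = 4)
  d <- array(0, c(1, 4, 4)); d[1, 1, 1] <- NA
  expect_error(displacement_to_phase(d, cfg, g), "finite")
})
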