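g <- scan_geometry()

test_that("phase difference wraps consecutive-frame differences", {
  m <- rbind(c(0, pi / 2, pi), c(1, 1, 1))
  d <- phase_difference(m)
  expect_equal(dim(d), c(2, 2))
  expect_equal(d[1, ], c(pi / 2, pi / 2))
  expect_equal(d[2, ], c(0, 0))

  # wrap(-6) = 2*pi - 6
  m2 <- rbind(c(3, -3))
  expect_equal(phase_difference(m2)[1, 1], 2 * pi - 6)

  expect_error(phase_difference(matrix(1, 4, 1)), "time extent")
})

test_that("phase difference converts to micrometre displacement", {
  expect_equal(phase_to_displacement(0, g), 0)
  # dphi = pi, lambda = 1.310 um, n = 1.38 -> 1.310 / (4 * 1.38) um
  expect_equal(phase_to_displacement(pi, g, 1.38), 1.310 / (4 * 1.38),
               tolerance = 1e-12)
  # inverse identity: the dphi that encodes 1 um maps back to 1 um
  lam <- g$wavelength_nm * 1e-3
  expect_equal(phase_to_displacement(4 * pi * 1.38 / lam, g, 1.38), 1)
  expect_error(phase_to_displacement(1, g, refractive_index = 0), "> 0")
})

test_that("directional filter separates forward from backward waves", {
  fwd <- plane_wave(48, 40, direction = "forward")
  bwd <- plane_wave(48, 40, direction = "backward")
  f <- directional_filter(fwd, "forward")
  expect_lt(sqrt(sum((f - fwd)^2) / sum(fwd^2)), 1e-6)
  b <- directional_filter(bwd, "forward")
  expect_lt(sum(b^2) / sum(bwd^2), 1e-6)
  mix <- directional_filter(fwd + bwd, "forward")
  expect_lt(sqrt(sum((mix - fwd)^2) / sum(fwd^2)), 0.01)
  # and the mirrored direction
  expect_lt(sqrt(sum((directional_filter(bwd, "backward") - bwd)^2) /
                   sum(bwd^2)), 1e-6)
})

test_that("directional filter is idempotent", {
  set.seed(3)
  x <- matrix(rnorm(32 * 24), 32)
  once <- directional_filter(x)
  twice <- directional_filter(once)
  expect_lt(sqrt(sum((twice - once)^2) / sum(once^2)), 1e-10)
})

test_that("low-pass keeps DC and low tones, rejects high tones", {
  dc <- matrix(2.5, 4, 600)
  expect_equal(lowpass_filter(dc, geometry = g), dc, tolerance = 1e-8)

  tt <- (0:1023) / g$aline_rate_hz
  mid <- 200:800
  s500 <- matrix(sin(2 * pi * 500 * tt), 2, 1024, byrow = TRUE)
  s10k <- matrix(sin(2 * pi * 10000 * tt), 2, 1024, byrow = TRUE)
  expect_gte(max(abs(lowpass_filter(s500, geometry = g)[1, mid])), 0.99)
  expect_lte(max(abs(lowpass_filter(s10k, geometry = g)[1, mid])), 0.1)

  expect_error(lowpass_filter(dc, cutoff_hz = 5e4, geometry = g), "Nyquist")
})

test_that("median filter removes impulses and matches the naive oracle", {
  const <- array(7, c(3, 9, 9))
  expect_equal(median_filter_3d(const, c(1, 3, 3)), const)

  imp <- const; imp[2, 5, 5] <- 100
  expect_equal(median_filter_3d(imp, c(1, 3, 3)), const)

  set.seed(4)
  a <- array(rnorm(5 * 9 * 7), c(5, 9, 7))
  expect_equal(median_filter_3d(a, c(3, 5, 3)), naive_median3d(a, c(3, 5, 3)))

  expect_error(median_filter_3d(a, c(2, 3, 3)), "odd")
})

test_that("particle normalization scales live columns to unit peak", {
  m <- rbind(c(0.5, 2, 1), c(0, 0, 0), c(-1, -2, -0.5))
  ns <- normalize_particles(m)
  expect_equal(max(ns$values[1, ]), 1)
  expect_equal(ns$dead, c(FALSE, TRUE, TRUE))  # all-negative column is dead too
  expect_equal(ns$values[2, ], c(0, 0, 0))
  set.seed(9)
  r <- normalize_particles(matrix(rnorm(50, mean = 1), 5))
  expect_equal(apply(r$values[!r$dead, , drop = FALSE], 1, max),
               rep(1, sum(!r$dead)))
})

test_that("the pipeline applies filters in the documented order", {
  cfg <- sim_config(velocity_mps = 5, depth_px = 3, lateral_px = 48,
                    time_px = 96, seed = 2)
  fld <- displacement_pipeline(simulate_volume(cfg, g), g)
  expect_equal(fld$filters_applied,
               c("phase_difference", "displacement", "directional_forward",
                 "lowpass_2000", "median_1x11x5", "normalize"))
  expect_equal(dim(fld$values), c(3, 48, 95))
  nd <- displacement_pipeline(simulate_volume(cfg, g), g,
                              directional = FALSE, max_layers = 2)
  expect_false("directional_forward" %in% nd$filters_applied)
  expect_equal(dim(nd$values)[1], 2)
})

test_that("noisy ridges stay within a few samples of the oracle ridge", {
  mk <- function(noise, seed) {
    cfg <- sim_config(velocity_mps = 4, depth_px = 1, lateral_px = 320,
                      time_px = 512, n_pulses = 1, noise_sigma_rad = noise,
                      seed = seed)
    displacement_pipeline(simulate_volume(cfg, g), g)
  }
  r0 <- track_layer1(mk(0, 9))$peak_time_sample
  for (s in c(11, 22)) {
    r <- track_layer1(mk(0.3, s))$peak_time_sample
    # the low-passed packet has a ~7-sample flat top, so argmax carries a
    # ~3-sample ambiguity independent of noise; 5 is the measured envelope
    expect_lte(max(abs(r - r0)), 5)
  }
})
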