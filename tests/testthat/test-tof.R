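g <- scan_geometry()

# Build a displacement slice with a known argmax ridge t(x).
ridge_slice <- function(tpos, nt) {
  L <- length(tpos)
  vals <- matrix(0, L, nt)
  for (x in seq_len(L)) vals[x, tpos[x]] <- 1
  as_slice(vals)
}

test_that("wavefront tracking recovers a synthetic ridge exactly", {
  tpos <- 10 + 2 * (1:40)
  tr <- track_wavefront(ridge_slice(tpos, 100))
  expect_equal(tr$peak_time_sample, tpos)
  expect_true(all(tr$valid_mask))
})

test_that("tied maxima resolve to the earliest sample and dead columns mask out", {
  vals <- matrix(0, 3, 10)
  vals[1, c(4, 7)] <- 1          # tie -> earliest
  vals[2, 5] <- 1
  tr <- track_wavefront(as_slice(vals, dead = c(FALSE, FALSE, TRUE)))
  expect_equal(tr$peak_time_sample[1], 4L)
  expect_false(tr$valid_mask[3])

  all_dead <- as_slice(matrix(0, 5, 10), dead = rep(TRUE, 5))
  tr2 <- track_wavefront(all_dead)
  expect_false(any(tr2$valid_mask))
  expect_error(fit_velocity(tr2, g), ">= 3")
})

test_that("lateral and time windows are validated", {
  sl <- ridge_slice(10 + (1:20), 40)
  expect_error(track_wavefront(sl, lateral_window = c(5, 3)), "window")
  expect_error(track_wavefront(sl, lateral_window = c(0, 10)), "window")
  expect_error(track_wavefront(sl, time_window = c(10, 100)), "time window")
  tr <- track_wavefront(sl, lateral_window = c(5, 10))
  expect_equal(sum(tr$valid_mask), 6)
})

test_that("multi-pulse tracking restricts to the first inter-pulse interval", {
  # second half of the ridge aliases onto a later pulse
  tpos <- c(10 + (1:20), 10 + 46 + 60 + (1:20))
  tr <- track_wavefront(ridge_slice(tpos, 160), pulse_period_samples = 46)
  expect_true(all(tr$valid_mask[1:20]))
  expect_false(any(tr$valid_mask[21:40]))
})

test_that("unit slope converts to the geometry's unit velocity", {
  tr <- track_wavefront(ridge_slice(20 + (1:60), 120))
  est <- fit_velocity(tr, g)
  expect_equal(est$velocity_mps, px_per_sample_velocity(g), tolerance = 1e-9)
  expect_true(est$converged)
  expect_equal(est$r_squared, 1)
  expect_equal(est$n_points, 60)
})

test_that("robust refinement survives 10% gross outliers", {
  set.seed(31)
  for (rep in 1:5) {
    L <- 100
    tpos <- round(15 + 0.8 * (1:L))
    out_idx <- sample(L, 10)
    tpos[out_idx] <- tpos[out_idx] + sample(c(-60, 40, 80), 10, replace = TRUE)
    est <- fit_velocity(track_wavefront(ridge_slice(pmax(tpos, 1), 220)), g)
    v_true <- px_per_sample_velocity(g) / 0.8
    expect_lt(abs(est$velocity_mps - v_true) / v_true, 0.02)
  }
})

test_that("a constant time offset leaves the velocity unchanged", {
  tpos <- 10 + 3 * (1:30)
  v1 <- fit_velocity(track_wavefront(ridge_slice(tpos, 200)), g)$velocity_mps
  v2 <- fit_velocity(track_wavefront(ridge_slice(tpos + 50, 200)), g)$velocity_mps
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("flat or backward ridges yield non-converged estimates", {
  backward <- fit_velocity(track_wavefront(ridge_slice(100 - 2 * (1:30), 120)), g)
  expect_false(backward$converged)
  expect_true(is.na(backward$velocity_mps))
})

test_that("profiles stop at the layer cap and summarize converged layers", {
  nz <- 310
  vals <- array(0, c(nz, 12, 40))
  for (x in 1:12) vals[, x, 5 + 2 * x] <- 1
  fld <- structure(list(values = vals, dead = matrix(FALSE, nz, 12),
                        filters_applied = character(), geometry = g,
                        time_guard = 0L),
                   class = "displacement_field")
  prof <- profile_volume(fld, g)
  expect_equal(nrow(prof$estimates), 300)   # cap
  expect_equal(prof$summary$n, 300)
  expect_equal(prof$summary$mean, px_per_sample_velocity(g) / 2,
               tolerance = 1e-9)
  prof5 <- profile_volume(fld, g, max_layers = 5)
  expect_equal(nrow(prof5$estimates), 5)
})

test_that("homogeneous noiseless volumes profile to the true velocity", {
  cfg <- sim_config(velocity_mps = 5, depth_px = 4, lateral_px = 320,
                    time_px = 512, n_pulses = 1, noise_sigma_rad = 0,
                    seed = 8)
  fld <- displacement_pipeline(simulate_volume(cfg, g), g,
                               directional = FALSE)
  prof <- profile_volume(fld, g)
  expect_equal(prof$summary$n, 4)
  expect_lt(max(abs(prof$estimates$velocity_mps - 5) / 5), 0.02)
  expect_lt(prof$summary$sd, 0.1)
})

test_that("a lateral window recovers the lesion velocity, not the background", {
  seg <- data.frame(lateral_start_px = c(1, 161), lateral_end_px = c(160, 320),
                    velocity_mps = c(4, 9))
  cfg <- sim_config(velocity_mps = seg, depth_px = 2, lateral_px = 320,
                    time_px = 512, n_pulses = 1, noise_sigma_rad = 0,
                    seed = 8)
  fld <- displacement_pipeline(simulate_volume(cfg, g), g,
                               directional = FALSE)
  prof <- profile_volume(fld, g, lateral_window = c(181, 310))
  expect_lt(abs(prof$summary$mean - 9) / 9, 0.05)
  expect_gt(prof$summary$mean, 7)   # clearly the lesion, not the background
})

test_that("noise at 0.5 rad leaves the median layer error under 10%", {
  cfg <- sim_config(velocity_mps = 6, depth_px = 4, lateral_px = 320,
                    time_px = 512, n_pulses = 1, noise_sigma_rad = 0.5,
                    seed = 21)
  fld <- displacement_pipeline(simulate_volume(cfg, g), g)
  prof <- profile_volume(fld, g)
  err <- abs(prof$estimates$velocity_mps - 6) / 6
  expect_lte(median(err, na.rm = TRUE), 0.10)
})
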