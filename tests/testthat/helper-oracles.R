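# Shared oracles and fixtures, built in code.

# Naive sliding-median oracle (reflection padding), independent of the
# package's C++ implementation.
naive_median3d <- function(a, kern) {
  d <- dim(a)
  out <- a
  refl <- function(i, n) {
    while (any(i < 1 | i > n)) {
      i[i < 1] <- 1 - i[i < 1]
      i[i > n] <- 2 * n + 1 - i[i > n]
    }
    i
  }
  h <- kern %/% 2
  for (z in seq_len(d[1])) {
    zi <- refl(z + (-h[1]:h[1]), d[1])
    for (y in seq_len(d[2])) {
      yi <- refl(y + (-h[2]:h[2]), d[2])
      for (t in seq_len(d[3])) {
        ti <- refl(t + (-h[3]:h[3]), d[3])
        out[z, y, t] <- median(a[zi, yi, ti])
      }
    }
  }
  out
}

# Periodic plane wave on an L x T grid travelling forward (+x with t) or
# backward; integer cycle counts keep it exactly periodic for the DFT.
plane_wave <- function(L, T, kx = 3, ft = 5, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  s <- if (direction == "forward") -1 else 1
  x <- matrix(rep(seq_len(L), T), L)
  t <- matrix(rep(seq_len(T), each = L), L)
  cos(2 * pi * (kx * x / L + s * ft * t / T))
}

# Wrap a plain matrix as a displacement_slice for tracking tests.
as_slice <- function(values, dead = NULL) {
  if (is.null(dead)) dead <- rep(FALSE, nrow(values))
  structure(list(values = values, dead = dead, depth_index = 1L,
                 filters_applied = character()),
            class = "displacement_slice")
}

# Track the first depth layer of a displacement_field with its settling
# guard applied.
track_layer1 <- function(fld, ...) {
  nt <- dim(fld$values)[3]
  tw <- c(fld$time_guard + 1L, nt - fld$time_guard)
  track_wavefront(as_slice(fld$values[1, , ], fld$dead[1, ]),
                  time_window = tw, ...)
}

# Cache shared across test files (the scaled-down trained model is reused
# by several acceptance checks).
.sawoce_test_cache <- new.env(parent = emptyenv())

# Desk-scale velocity-regression study: 500 simulated acquisitions, 6
# depth layers each, 48x48 slices, velocities Uniform(2, 16) m/s, 4 kHz
# packet, oracle labels; VP-Net-S trained with the standard recipe
# (Adam 1e-3, batch 32, MAE, patience 30) capped at 40 epochs.
desk_scale_study <- function() {
  if (!is.null(.sawoce_test_cache$study)) return(.sawoce_test_cache$study)
  vels <- local({ set.seed(101); runif(500, 2, 16) })
  configs <- lapply(seq_along(vels), function(i)
    sim_config(velocity_mps = vels[i], depth_px = 6, lateral_px = 48,
               time_px = 48, pulse_hz = 4000, seed = 5000 + i))
  ds <- make_dataset(configs, seed = 11, labels = "oracle", slice_size = 48)
  model <- build_vpnet("S", input_size = 48, seed = 3)
  model <- train_vpnet(model, ds$train, ds$val,
                       train_config(max_epochs = 40, patience = 30, seed = 4))
  .sawoce_test_cache$study <- list(dataset = ds, model = model,
                                   configs = configs, velocities = vels)
  .sawoce_test_cache$study
}

# Attention study for Grad-CAM: same recipe at 48x48 but with a sharp
# (12 kHz) packet so the wavefront is a localized stripe the ridge-band
# overlap test can identify; 300 acquisitions, 4 depth layers each.
gradcam_study <- function() {
  if (!is.null(.sawoce_test_cache$gradcam)) return(.sawoce_test_cache$gradcam)
  vels <- local({ set.seed(202); runif(300, 2, 16) })
  configs <- lapply(seq_along(vels), function(i)
    sim_config(velocity_mps = vels[i], depth_px = 4, lateral_px = 48,
               time_px = 48, pulse_hz = 12000, seed = 9000 + i))
  ds <- make_dataset(configs, seed = 12, labels = "oracle", slice_size = 48)
  model <- build_vpnet("S", input_size = 48, seed = 6)
  model <- train_vpnet(model, ds$train, ds$val,
                       train_config(max_epochs = 25, patience = 20, seed = 7))
  .sawoce_test_cache$gradcam <- list(model = model, pulse_hz = 12000)
  .sawoce_test_cache$gradcam
}

# Noise-free, speckle-free 48x48 slice showing only the wave packet.
clean_packet_slice <- function(v, pulse_hz, amplitude_rad = 1.5,
                               geometry = scan_geometry()) {
  cfg <- sim_config(velocity_mps = v, depth_px = 1, lateral_px = 48,
                    time_px = 48, pulse_hz = pulse_hz, noise_sigma_rad = 0)
  d <- simulate_displacement(cfg, geometry)[1, , ]
  normalize_phase(wrap_phase(amplitude_rad * d / max(abs(d))))
}
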