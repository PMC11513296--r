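#' Configuration of a synthetic OCE acquisition
#'
#' Describes one simulated M-B acquisition: the SAW velocity field (uniform
#' or piecewise along the lateral axis, e.g. a stiff lesion in a softer
#' background), the actuator excitation, the phase-modulation amplitude and
#' the noise/artifact structure of in-vivo raw phase data.
#'
#' The excitation emulates a square-wave driven piezoelectric actuator:
#' rising edges at `excitation_hz` (default 2 kHz, 60% duty cycle) each
#' launch a surface wave packet. The packet itself is a single-cycle
#' Gaussian-windowed cosine of centre frequency `pulse_hz` (default 1 kHz,
#' below the 2 kHz low-pass used downstream so the packet survives
#' filtering).
#'
#' @param velocity_mps SAW velocity in m/s. Either a single positive number
#'   or a data.frame with columns `lateral_start_px`, `lateral_end_px`,
#'   `velocity_mps` whose segments tile `1..lateral_px` without overlap.
#' @param excitation_hz actuator repetition rate, Hz.
#' @param duty_cycle square-wave duty cycle, in (0, 1).
#' @param amplitude_rad peak phase modulation of the wave packet, radians.
#' @param noise_sigma_rad standard deviation of additive i.i.d. phase noise,
#'   radians.
#' @param lateral_attenuation_per_mm,depth_attenuation_per_mm exponential
#'   amplitude decay rates, 1/mm.
#' @param motion_artifact one of `"none"`, `"drift"` (slow bulk phase ramp,
#'   at most pi over the window) or `"jump"` (up to two random phase steps).
#' @param depth_px,lateral_px,time_px volume extent in pixels.
#' @param pulse_hz centre frequency of the wave packet, Hz.
#' @param n_pulses number of excitation pulses to simulate (`NULL` = the
#'   full pulse train covering the time window). Use 1 for single-pulse
#'   time-of-flight experiments.
#' @param seed integer seed making the speckle/noise draw reproducible.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(velocity_mps = 5,
                       excitation_hz = 2000,
                       duty_cycle = 0.6,
                       amplitude_rad = 1.5,
                       noise_sigma_rad = 0.2,
                       lateral_attenuation_per_mm = 0.05,
                       depth_attenuation_per_mm = 1,
                       motion_artifact = c("none", "drift", "jump"),
                       depth_px = 512, lateral_px = 512, time_px = 512,
                       pulse_hz = 1000, n_pulses = NULL, seed = NULL) {
  motion_artifact <- match.arg(motion_artifact)
  stopifnot(amplitude_rad >= 0, noise_sigma_rad >= 0,
            duty_cycle > 0, duty_cycle < 1,
            depth_px >= 1, lateral_px >= 1, time_px >= 2,
            excitation_hz > 0, pulse_hz > 0)
  if (is.data.frame(velocity_mps)) {
    seg <- velocity_mps[order(velocity_mps$lateral_start_px), , drop = FALSE]
    req <- c("lateral_start_px", "lateral_end_px", "velocity_mps")
    if (!all(req %in% names(seg))) {
      stop("piecewise velocity needs columns ", paste(req, collapse = ", "))
    }
    bad <- which(seg$velocity_mps <= 0)
    if (length(bad)) {
      stop(sprintf("velocity must be > 0; segment %d (lateral %d-%d) has %g m/s",
                   bad[1], seg$lateral_start_px[bad[1]],
                   seg$lateral_end_px[bad[1]], seg$velocity_mps[bad[1]]))
    }
    if (seg$lateral_start_px[1] != 1 ||
        seg$lateral_end_px[nrow(seg)] != lateral_px ||
        (nrow(seg) > 1 &&
         any(seg$lateral_start_px[-1] != seg$lateral_end_px[-nrow(seg)] + 1))) {
      stop("velocity segments must tile 1..lateral_px without gaps or overlap")
    }
  } else {
    if (!is.numeric(velocity_mps) || length(velocity_mps) != 1 ||
        velocity_mps <= 0) {
      stop("velocity must be > 0; uniform segment has ",
           format(velocity_mps), " m/s")
    }
  }
  structure(
    list(velocity_mps = velocity_mps, excitation_hz = excitation_hz,
         duty_cycle = duty_cycle, amplitude_rad = amplitude_rad,
         noise_sigma_rad = noise_sigma_rad,
         lateral_attenuation_per_mm = lateral_attenuation_per_mm,
         depth_attenuation_per_mm = depth_attenuation_per_mm,
         motion_artifact = motion_artifact,
         depth_px = depth_px, lateral_px = lateral_px, time_px = time_px,
         pulse_hz = pulse_hz, n_pulses = n_pulses, seed = seed),
    class = "sim_config"
  )
}

#' Per-lateral-pixel velocity profile of a simulation config
#'
#' @param config a [sim_config()].
#' @return numeric vector of length `lateral_px`, m/s.
#' @export
velocity_profile <- function(config) {
  if (is.data.frame(config$velocity_mps)) {
    seg <- config$velocity_mps
    v <- numeric(config$lateral_px)
    for (i in seq_len(nrow(seg))) {
      v[seg$lateral_start_px[i]:seg$lateral_end_px[i]] <- seg$velocity_mps[i]
    }
    v
  } else {
    rep(config$velocity_mps, config$lateral_px)
  }
}

#' Simulate the axial displacement field of a travelling SAW packet
#'
#' Each rising edge of the square-wave excitation launches a single-cycle
#' Gaussian-windowed cosine packet that travels along the lateral axis with
#' the local velocity `v(x)`. The arrival time at lateral position `x` is
#' the cumulative travel time `sum(dx / v)`, so the space-time argmax ridge
#' of the packet has slope `1/v(x)` in physical units within each velocity
#' segment. Amplitude decays as `exp(-lateral_attenuation * x_mm) *
#' exp(-depth_attenuation * z_mm)`; the surface peak is 1 micrometre.
#'
#' @param config a [sim_config()].
#' @param geometry a [scan_geometry()].
#' @return numeric array `[depth_px, lateral_px, time_px]` of axial
#'   displacement in micrometres (deterministic; no noise at this stage).
#' @export
simulate_displacement <- function(config, geometry = scan_geometry()) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$lateral_px; D <- config$depth_px; T <- config$time_px
  dt <- 1 / geometry$aline_rate_hz
  dx_m <- geometry$lateral_um_per_px * 1e-6
  v <- velocity_profile(config)
  # cumulative travel time to each lateral pixel (s); slope d t / d x = 1/v
  t_arr <- c(0, cumsum(dx_m / v[-L]))
  t_s <- (seq_len(T) - 1) * dt

  period <- 1 / config$excitation_hz
  n_max <- floor(t_s[T] / period) + 1L
  n_p <- if (is.null(config$n_pulses)) n_max else min(config$n_pulses, n_max)
  onsets <- (seq_len(n_p) - 1) * period

  f_c <- config$pulse_hz
  sig <- 1 / (2 * f_c)                      # ~single-cycle envelope
  lag0 <- 2 * sig                           # causal: packet rises after onset
  field <- matrix(0, L, T)
  for (t0 in onsets) {
    tau <- outer(-t_arr - t0 - lag0, t_s, `+`)  # [L, T] lag of each sample
    field <- field + cos(2 * pi * f_c * tau) * exp(-tau^2 / (2 * sig^2))
  }
  x_mm <- (seq_len(L) - 1) * geometry$lateral_um_per_px * 1e-3
  z_mm <- (seq_len(D) - 1) * geometry$axial_um_per_px * 1e-3
  field <- field * exp(-config$lateral_attenuation_per_mm * x_mm)
  disp <- array(0, c(D, L, T))
  datt <- exp(-config$depth_attenuation_per_mm * z_mm)
  # outer product over depth: disp[z, x, t] = datt[z] * field[x, t]
  disp[] <- outer(datt, field)
  disp
}

#' Encode a displacement field as a wrapped raw phase volume
#'
#' Inverts the phase-difference displacement measurement of phase-sensitive
#' OCT: the wave modulation enters the phase as `(4 pi / lambda) * d`,
#' rescaled so its peak equals `amplitude_rad`; a static speckle phase
#' offset (uniform on \eqn{[-\pi,\pi)}, constant in time per (depth,
#' lateral) column), i.i.d. Gaussian phase noise and an optional bulk
#' motion term (drift ramp or step jumps) are added, and the sum is wrapped
#' into \eqn{[-\pi, \pi)}. Reproducible given `config$seed`.
#'
#' @param displacement array `[depth, lateral, time]`, micrometres; all
#'   values must be finite.
#' @param config a [sim_config()].
#' @param geometry a [scan_geometry()].
#' @return an `oce_volume`: list with elements `phase` (array
#'   `[depth, lateral, time]`, radians in \eqn{[-\pi,\pi)}), `geometry`,
#'   `oracle_velocity` (list with `segments` and `per_lateral`) and
#'   `config`.
#' @export
displacement_to_phase <- function(displacement, config,
                                  geometry = scan_geometry()) {
  stopifnot(is.array(displacement), length(dim(displacement)) == 3)
  if (!all(is.finite(displacement))) stop("displacement must be finite")
  d <- dim(displacement)
  D <- d[1]; L <- d[2]; T <- d[3]
  peak <- max(abs(displacement))
  scale <- if (peak > 0) config$amplitude_rad / peak else 0

  phase <- with_seed(config$seed, {
    phi0 <- matrix(runif(D * L, -pi, pi), D, L)   # static speckle phase
    ph <- array(phi0, d)                          # recycled over time
    ph <- ph + scale * displacement
    if (config$noise_sigma_rad > 0) {
      ph <- ph + rnorm(length(ph), sd = config$noise_sigma_rad)
    }
    m <- motion_term(config$motion_artifact, T)
    if (!is.null(m)) ph <- ph + rep(m, each = D * L)
    wrap_phase(ph)
  })

  seg <- if (is.data.frame(config$velocity_mps)) {
    config$velocity_mps
  } else {
    data.frame(lateral_start_px = 1L, lateral_end_px = L,
               velocity_mps = config$velocity_mps)
  }
  structure(
    list(phase = phase, geometry = geometry,
         oracle_velocity = list(segments = seg,
                                per_lateral = velocity_profile(config)),
         config = config),
    class = "oce_volume"
  )
}

# Bulk motion-artifact phase term m(t), or NULL for "none".
motion_term <- function(kind, T) {
  switch(kind,
    none = NULL,
    drift = {  # slow linear ramp, magnitude <= pi over the window
      amp <- runif(1, pi / 2, pi) * sample(c(-1, 1), 1)
      amp * (seq_len(T) - 1) / (T - 1)
    },
    jump = {   # up to two step discontinuities
      n_j <- sample(1:2, 1)
      m <- numeric(T)
      for (i in seq_len(n_j)) {
        at <- sample(2:T, 1)
        m[at:T] <- m[at:T] + runif(1, -pi, pi)
      }
      m
    }
  )
}

#' Simulate a complete raw OCE phase volume
#'
#' Convenience wrapper: [simulate_displacement()] followed by
#' [displacement_to_phase()].
#'
#' @inheritParams simulate_displacement
#' @return an `oce_volume` (see [displacement_to_phase()]).
#' @examples
#' vol <- simulate_volume(sim_config(velocity_mps = 5, depth_px = 4,
#'                                   lateral_px = 64, time_px = 64, seed = 1))
#' dim(vol$phase)
#' @export
simulate_volume <- function(config, geometry = scan_geometry()) {
  displacement_to_phase(simulate_displacement(config, geometry),
                        config, geometry)
}

#' @export
print.oce_volume <- function(x, ...) {
  d <- dim(x$phase)
  cat(sprintf("OCE raw phase volume: %d depth x %d lateral x %d time\n",
              d[1], d[2], d[3]))
  if (!is.null(x$oracle_velocity)) {
    v <- unique(x$oracle_velocity$segments$velocity_mps)
    cat("  oracle velocity (m/s):", paste(v, collapse = ", "), "\n")
  }
  invisible(x)
}
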