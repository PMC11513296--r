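#' Temporal phase difference between consecutive A-lines
#'
#' Computes `wrap(phase[, t+1] - phase[, t])` along the time axis, the
#' phase-sensitive OCT measurement of inter-frame axial motion. The static
#' speckle phase cancels in the difference.
#'
#' @param x matrix `[lateral, time]` or array `[depth, lateral, time]` of
#'   wrapped phase, radians.
#' @return same structure with time extent reduced by one, wrapped into
#'   \eqn{[-\pi, \pi)}.
#' @export
phase_difference <- function(x) {
  nd <- length(dim(x))
  if (is.matrix(x)) {
    if (ncol(x) < 2) stop("time extent must be >= 2")
    wrap_phase(x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE])
  } else if (nd == 3) {
    if (dim(x)[3] < 2) stop("time extent must be >= 2")
    wrap_phase(x[, , -1, drop = FALSE] - x[, , -dim(x)[3], drop = FALSE])
  } else {
    stop("expected a [lateral, time] matrix or [depth, lateral, time] array")
  }
}

#' Convert phase difference to axial displacement
#'
#' `d = dphi * lambda0 / (4 pi n)` with the centre wavelength `lambda0`
#' from the scan geometry and tissue refractive index `n`. The absolute
#' scale cancels later in particle normalization, so it does not affect
#' velocity estimates, but it is applied consistently.
#'
#' @param dphi wrapped phase difference, radians (any shape).
#' @param geometry a [scan_geometry()].
#' @param refractive_index tissue refractive index (default 1.38, soft
#'   tissue).
#' @return axial displacement in micrometres, same shape as `dphi`.
#' @export
phase_to_displacement <- function(dphi, geometry = scan_geometry(),
                                  refractive_index = 1.38) {
  if (refractive_index <= 0) stop("refractive index must be > 0")
  lambda_um <- geometry$wavelength_nm * 1e-3
  dphi * lambda_um / (4 * pi * refractive_index)
}

#' Directional (f-k) wave filter
#'
#' Separates forward- from backward-travelling wave components in the 2-D
#' Fourier (lateral wavenumber x temporal frequency) domain. A wave
#' travelling toward increasing lateral position occupies the quadrants
#' where the signs of wavenumber and frequency are opposite; the filter
#' zeroes the two quadrants of the rejected direction and keeps the DC /
#' Nyquist rows and columns, then returns the real part of the inverse
#' transform. Applying the filter twice equals applying it once (the
#' quadrant mask is idempotent).
#'
#' @param disp matrix `[lateral, time]` of displacement (any real field).
#' @param direction propagation direction to keep: `"forward"` (increasing
#'   lateral position with time) or `"backward"`.
#' @return filtered real matrix, same shape.
#' @export
directional_filter <- function(disp, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  stopifnot(is.matrix(disp))
  sx <- freq_sign(nrow(disp))
  st <- freq_sign(ncol(disp))
  s <- outer(sx, st)                 # sign of wavenumber x frequency
  keep <- if (direction == "forward") s <= 0 else s >= 0
  F <- stats::fft(disp)
  Re(stats::fft(F * keep, inverse = TRUE)) / length(disp)
}

# Sign of the DFT frequency at each index; 0 at DC and (even n) Nyquist.
freq_sign <- function(n) {
  j <- 0:(n - 1)
  f <- ifelse(j <= n %/% 2, j, j - n)
  if (n %% 2 == 0) f[n %/% 2 + 1] <- 0
  sign(f)
}

#' Zero-phase temporal low-pass filter
#'
#' 4th-order Butterworth low-pass (default cutoff 2 kHz) applied
#' forward-backward along the time axis, so arrival times used by the
#' time-of-flight fit are not shifted. Edge transients are suppressed by
#' odd-symmetric signal extension before filtering.
#'
#' @param disp matrix `[lateral, time]`.
#' @param cutoff_hz cutoff frequency, Hz; must be below Nyquist.
#' @param geometry a [scan_geometry()] (supplies the sampling rate).
#' @param order filter order of each pass.
#' @return filtered matrix, same shape.
#' @export
lowpass_filter <- function(disp, cutoff_hz = 2000,
                           geometry = scan_geometry(), order = 4) {
  stopifnot(is.matrix(disp))
  fs <- geometry$aline_rate_hz
  if (cutoff_hz >= fs / 2) {
    stop(sprintf("cutoff %g Hz is not below Nyquist (%g Hz)",
                 cutoff_hz, fs / 2))
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  # pad by ~3 filter time constants so start-up transients settle
  filtfilt_rows(disp, bf$b, bf$a, pad = round(3 * fs / cutoff_hz))
}

# Steady-state initial condition of an IIR filter for unit input, so the
# step response starts at its asymptote (lfilter_zi construction).
iir_steady_state <- function(b, a) {
  n <- max(length(a), length(b))
  aa <- c(a, numeric(n - length(a))) / a[1]
  bb <- c(b, numeric(n - length(b))) / a[1]
  if (n == 1) return(numeric(0))
  comp <- rbind(-aa[-1], cbind(diag(1, n - 2, n - 2), numeric(n - 2)))
  solve(diag(n - 1) - t(comp), bb[-1] - aa[-1] * bb[1])
}

# Forward-backward IIR filtering of each row (time axis = columns),
# with odd-symmetric extension to suppress edge transients.
filtfilt_rows <- function(x, b, a, pad = 24) {
  T <- ncol(x)
  pad <- min(max(3 * (max(length(a), length(b)) - 1), pad), T - 1)
  zi <- iir_steady_state(b, a)
  left <- 2 * x[, 1] - x[, (pad + 1):2, drop = FALSE]
  right <- 2 * x[, T] - x[, (T - 1):(T - pad), drop = FALSE]
  ext <- cbind(left, x, right)
  y <- iir_rows_cpp(ext, b, a, zi)
  y <- iir_rows_cpp(y[, ncol(y):1, drop = FALSE], b, a, zi)
  y <- y[, ncol(y):1, drop = FALSE]
  y[, pad + seq_len(T), drop = FALSE]
}

#' 3-D sliding-window median filter
#'
#' Median filter over a `[depth, lateral, time]` volume with an odd kernel,
#' default `(1, 11, 5)`: an 11 (lateral) x 5 (time) window applied
#' per depth layer, which preserves depth-local velocity structure. Edges
#' are handled by reflection.
#'
#' @param x 3-D array `[depth, lateral, time]` (a matrix is treated as a
#'   single depth layer).
#' @param kernel integer vector of three odd window extents.
#' @return filtered array (or matrix, matching the input).
#' @export
median_filter_3d <- function(x, kernel = c(1, 11, 5)) {
  was_matrix <- is.matrix(x)
  if (was_matrix) x <- array(x, c(1, dim(x)))
  stopifnot(is.array(x), length(dim(x)) == 3, length(kernel) == 3)
  if (any(kernel %% 2 != 1) || any(kernel < 1)) {
    stop("median kernel extents must be odd positive integers")
  }
  d <- dim(x)
  out <- median3d_cpp(as.double(x), d[1], d[2], d[3],
                      as.integer(kernel[1]), as.integer(kernel[2]),
                      as.integer(kernel[3]))
  if (was_matrix) out <- array(out, d)[1, , ] else out
}

#' Normalize displacement per particle
#'
#' Divides each lateral column (one "particle") by its own maximum over
#' time, so every live column peaks at exactly 1. Columns whose maximum
#' does not exceed `eps` carry no usable signal; they are zeroed and
#' flagged dead.
#'
#' @param disp matrix `[lateral, time]` of displacement.
#' @param depth_index depth-layer index recorded in the result.
#' @param filters_applied character vector of filter tags recorded in the
#'   result.
#' @param eps dead-column threshold.
#' @return a `displacement_slice`: list with `values` (matrix, live rows
#'   peak at 1), `dead` (logical per lateral position), `depth_index`,
#'   `filters_applied`.
#' @export
normalize_particles <- function(disp, depth_index = 0L,
                                filters_applied = character(), eps = 1e-12) {
  stopifnot(is.matrix(disp), all(is.finite(disp)))
  mx <- apply(disp, 1, max)
  dead <- mx <= eps
  vals <- disp
  vals[!dead, ] <- disp[!dead, , drop = FALSE] / mx[!dead]
  vals[dead, ] <- 0
  structure(
    list(values = vals, dead = dead, depth_index = as.integer(depth_index),
         filters_applied = c(filters_applied, "normalize")),
    class = "displacement_slice"
  )
}

#' Full raw-phase to displacement-field pipeline
#'
#' Runs the fixed filter sequence per depth layer: phase difference ->
#' displacement -> directional filter -> low-pass, then the 3-D median
#' filter across layers, then per-particle normalization. The applied
#' filter tags are recorded in order.
#'
#' @param vol an `oce_volume` or bare `[depth, lateral, time]` phase array.
#' @param geometry a [scan_geometry()] (taken from `vol` when present).
#' @param refractive_index tissue refractive index for the displacement
#'   scale.
#' @param directional apply the directional filter? (`TRUE` by default).
#' @param direction propagation direction kept by the directional filter.
#' @param cutoff_hz low-pass cutoff, Hz.
#' @param median_kernel odd kernel of the 3-D median filter.
#' @param max_layers process at most this many depth layers, starting at
#'   the surface.
#' @return a `displacement_field`: list with `values` (array
#'   `[layers, lateral, time - 1]` of normalized displacement), `dead`
#'   (logical matrix `[layers, lateral]`), `filters_applied`, `geometry`.
#' @export
displacement_pipeline <- function(vol, geometry = NULL,
                                  refractive_index = 1.38,
                                  directional = TRUE,
                                  direction = "forward",
                                  cutoff_hz = 2000,
                                  median_kernel = c(1, 11, 5),
                                  max_layers = Inf) {
  if (inherits(vol, "oce_volume")) {
    if (is.null(geometry)) geometry <- vol$geometry
    ph <- vol$phase
  } else {
    if (is.null(geometry)) geometry <- scan_geometry()
    ph <- vol
  }
  stopifnot(is.array(ph), length(dim(ph)) == 3)
  d <- dim(ph)
  nz <- min(d[1], max_layers)
  tags <- c("phase_difference", "displacement")
  out <- array(0, c(nz, d[2], d[3] - 1))
  for (z in seq_len(nz)) {
    dphi <- phase_difference(ph[z, , ])
    disp <- phase_to_displacement(dphi, geometry, refractive_index)
    if (directional) disp <- directional_filter(disp, direction)
    disp <- lowpass_filter(disp, cutoff_hz, geometry)
    out[z, , ] <- disp
  }
  if (directional) tags <- c(tags, paste0("directional_", direction))
  tags <- c(tags, sprintf("lowpass_%g", cutoff_hz))
  out <- median_filter_3d(out, median_kernel)
  tags <- c(tags, sprintf("median_%s", paste(median_kernel, collapse = "x")))
  dead <- matrix(FALSE, nz, d[2])
  for (z in seq_len(nz)) {
    ns <- normalize_particles(out[z, , ], depth_index = z)
    out[z, , ] <- ns$values
    dead[z, ] <- ns$dead
  }
  structure(
    list(values = out, dead = dead,
         filters_applied = c(tags, "normalize"), geometry = geometry,
         # settling band of the zero-phase low-pass at the time-axis edges
         # (about one filter time constant); wavefront tracking excludes it
         time_guard = round(geometry$aline_rate_hz / cutoff_hz)),
    class = "displacement_field"
  )
}
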