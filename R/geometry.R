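#' Scan geometry of a phase-sensitive OCT acquisition
#'
#' Bundles the sampling constants of the OCE system: axial and lateral
#' pixel pitch, A-line (temporal sampling) rate and source centre
#' wavelength. Defaults are the system constants of the acquisitions the
#' simulator emulates: 4.7 um/px axial, 21.7 um/px lateral, 92 kHz A-line
#' rate, 1310 nm centre wavelength.
#'
#' @param axial_um_per_px axial sampling distance, micrometres per pixel.
#' @param lateral_um_per_px lateral sampling distance, micrometres per pixel.
#' @param aline_rate_hz A-line rate (temporal sampling frequency), Hz.
#' @param wavelength_nm source centre wavelength, nanometres.
#' @return an object of class `scan_geometry`.
#' @examples
#' g <- scan_geometry()
#' px_per_sample_velocity(g) # m/s corresponding to 1 lateral px per sample
#' @export
scan_geometry <- function(axial_um_per_px = 4.7, lateral_um_per_px = 21.7,
                          aline_rate_hz = 92000, wavelength_nm = 1310) {
  vals <- c(axial_um_per_px, lateral_um_per_px, aline_rate_hz, wavelength_nm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all scan_geometry fields must be strictly positive and finite")
  }
  structure(
    list(axial_um_per_px = axial_um_per_px,
         lateral_um_per_px = lateral_um_per_px,
         aline_rate_hz = aline_rate_hz,
         wavelength_nm = wavelength_nm),
    class = "scan_geometry"
  )
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat("OCE scan geometry\n")
  cat(sprintf("  axial:   %.3g um/px\n", x$axial_um_per_px))
  cat(sprintf("  lateral: %.3g um/px\n", x$lateral_um_per_px))
  cat(sprintf("  A-line rate: %g Hz\n", x$aline_rate_hz))
  cat(sprintf("  wavelength:  %g nm\n", x$wavelength_nm))
  invisible(x)
}

#' Velocity of a unit space-time ridge slope
#'
#' The SAW velocity corresponding to a wavefront that advances one lateral
#' pixel per time sample: `lateral_um_per_px * 1e-6 * aline_rate_hz` m/s
#' (1.9964 m/s at the default geometry).
#'
#' @param geometry a [scan_geometry()].
#' @return velocity in m/s.
#' @export
px_per_sample_velocity <- function(geometry = scan_geometry()) {
  geometry$lateral_um_per_px * 1e-6 * geometry$aline_rate_hz
}
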