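#' Crop a raw phase volume to network-ready extent
#'
#' Crops the lateral and time axes to contiguous `size`-pixel windows
#' (default 320, the network input extent), leaving the depth axis
#' untouched. The lateral offset discards the region occupied by the head
#' of the piezoelectric actuator.
#'
#' @param vol an `oce_volume` (see [simulate_volume()]) or a bare 3-D array
#'   `[depth, lateral, time]`.
#' @param lateral_offset,time_offset 0-based window start on each axis.
#' @param size window extent in pixels on both cropped axes.
#' @return same type as `vol`, with lateral and time extents equal to
#'   `size`; the oracle velocity (if present) is windowed accordingly.
#' @examples
#' v <- array(0, c(2, 400, 330))
#' dim(crop_volume(v, lateral_offset = 40, time_offset = 0))
#' @export
crop_volume <- function(vol, lateral_offset = 96, time_offset = 0,
                        size = 320) {
  ph <- if (inherits(vol, "oce_volume")) vol$phase else vol
  stopifnot(is.array(ph), length(dim(ph)) == 3)
  d <- dim(ph)
  if (lateral_offset < 0 || lateral_offset + size > d[2]) {
    stop(sprintf(
      "crop window exceeds volume on lateral axis: offset %d + %d > %d",
      lateral_offset, size, d[2]))
  }
  if (time_offset < 0 || time_offset + size > d[3]) {
    stop(sprintf(
      "crop window exceeds volume on time axis: offset %d + %d > %d",
      time_offset, size, d[3]))
  }
  lat <- lateral_offset + seq_len(size)
  tim <- time_offset + seq_len(size)
  out <- ph[, lat, tim, drop = FALSE]
  if (inherits(vol, "oce_volume")) {
    vol$phase <- out
    if (!is.null(vol$oracle_velocity)) {
      vol$oracle_velocity$per_lateral <- vol$oracle_velocity$per_lateral[lat]
    }
    vol
  } else {
    out
  }
}

#' Linearly normalize wrapped phase to \eqn{[0, 1]}
#'
#' Maps radians in \eqn{[-\pi, \pi]} to the unit interval by
#' `x / pi * 0.5 + 0.5`, the scaling used to form network input slices:
#' \eqn{-\pi \to 0}, \eqn{0 \to 0.5}, \eqn{\pi \to 1}. Values outside
#' \eqn{[-\pi, \pi]} are rejected rather than silently wrapped, so that
#' upstream wrapping bugs surface here.
#'
#' @param x numeric array of wrapped phase, radians.
#' @return array of the same shape with values in \eqn{[0, 1]}.
#' @seealso [denormalize_phase()] for the exact inverse.
#' @export
normalize_phase <- function(x) {
  if (any(abs(x) > pi + 1e-12, na.rm = TRUE)) {
    stop("phase values outside [-pi, pi]; wrap before normalizing")
  }
  x / pi * 0.5 + 0.5
}

#' Invert the phase normalization
#'
#' @param x array of normalized values in \eqn{[0, 1]}.
#' @return wrapped phase in radians; `denormalize_phase(normalize_phase(p))`
#'   equals `p` to machine precision.
#' @export
denormalize_phase <- function(x) {
  (x - 0.5) * 2 * pi
}
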