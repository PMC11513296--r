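#' Track the main wavefront peak across lateral positions
#'
#' The main peak of the normalized displacement waveform is the maximum
#' along time at each lateral position (ties broken toward the earliest
#' sample, i.e. first arrival). Dead columns are masked out. When the
#' acquisition contains several excitation pulses, `pulse_period_samples`
#' restricts tracking to the first inter-pulse interval after the first
#' detected arrival, which avoids ridge aliasing between pulses.
#'
#' @param slice a `displacement_slice` (see [normalize_particles()]) or a
#'   plain `[lateral, time]` matrix.
#' @param lateral_window optional `c(start_px, end_px)` (1-based, inclusive)
#'   restricting tracking to a lateral region, e.g. a lesion.
#' @param pulse_period_samples optional inter-pulse spacing in time samples
#'   (46 at the default 2 kHz excitation and 92 kHz sampling).
#' @param time_window optional `c(first, last)` time-sample range searched
#'   for the peak, used to exclude filter settling bands at the window
#'   edges; default the full extent.
#' @return a `wavefront_track`: list with `peak_time_sample` (integer per
#'   lateral position, NA outside the window), `valid_mask`, and the window.
#' @export
track_wavefront <- function(slice, lateral_window = NULL,
                            pulse_period_samples = NULL,
                            time_window = NULL) {
  if (inherits(slice, "displacement_slice")) {
    vals <- slice$values
    dead <- slice$dead
  } else {
    stopifnot(is.matrix(slice))
    vals <- slice
    dead <- apply(vals, 1, function(r) max(abs(r)) <= 1e-12)
  }
  L <- nrow(vals)
  if (is.null(lateral_window)) lateral_window <- c(1L, L)
  w <- as.integer(lateral_window)
  if (w[1] < 1 || w[2] > L || w[1] > w[2]) {
    stop("empty or out-of-range lateral window")
  }
  nt <- ncol(vals)
  tw <- if (is.null(time_window)) c(1L, nt) else as.integer(time_window)
  if (tw[1] < 1 || tw[2] > nt || tw[1] > tw[2]) {
    stop("empty or out-of-range time window")
  }
  peak <- rep(NA_integer_, L)
  valid <- rep(FALSE, L)
  idx <- w[1]:w[2]
  for (x in idx) {
    if (!dead[x]) {
      # earliest index on ties (first arrival)
      peak[x] <- tw[1] - 1L + which.max(vals[x, tw[1]:tw[2]])
      valid[x] <- TRUE
    }
  }
  if (!is.null(pulse_period_samples) && any(valid)) {
    t0 <- min(peak[valid])
    valid <- valid & !is.na(peak) & peak >= t0 &
      peak < t0 + pulse_period_samples
  }
  structure(
    list(peak_time_sample = peak, valid_mask = valid,
         lateral_window = w),
    class = "wavefront_track"
  )
}

#' Fit SAW velocity to a tracked wavefront
#'
#' Least-squares regression of peak arrival time (samples) on lateral
#' position (pixels), with iterative robust refinement: points whose
#' residual exceeds 3 median-absolute-deviations are discarded and the
#' line refit, repeating until the relative change of the slope falls
#' below `tol` (default 1e-6) or `max_iter` (default 300) iterations.
#' The fitted slope `s` (samples per pixel) converts to velocity as
#' `lateral_um_per_px * 1e-6 * aline_rate_hz / s` m/s.
#'
#' @param track a `wavefront_track` from [track_wavefront()].
#' @param geometry a [scan_geometry()].
#' @param tol relative slope-change convergence threshold.
#' @param max_iter maximum robust-refinement iterations.
#' @return a `velocity_estimate`: list with `velocity_mps`,
#'   `intercept_sample`, `r_squared`, `n_points`, `converged`,
#'   `stopped_by` (`"tol"` or `"max_iter"`), `iterations`, `depth_index`.
#'   Non-positive or flat slopes yield a non-converged estimate with
#'   `velocity_mps = NA`.
#' @export
fit_velocity <- function(track, geometry = scan_geometry(),
                         tol = 1e-6, max_iter = 300) {
  stopifnot(inherits(track, "wavefront_track"))
  x <- which(track$valid_mask)
  t <- track$peak_time_sample[x]
  if (length(x) < 3) {
    stop(sprintf("need >= 3 valid track points, got %d", length(x)))
  }
  keep <- rep(TRUE, length(x))
  slope_prev <- NA_real_
  stopped_by <- "max_iter"
  iter <- 0L
  repeat {
    iter <- iter + 1L
    xi <- x[keep]; ti <- t[keep]
    if (length(xi) < 3) break
    sxx <- sum((xi - mean(xi))^2)
    slope <- sum((xi - mean(xi)) * (ti - mean(ti))) / sxx
    icpt <- mean(ti) - slope * mean(xi)
    resid <- ti - (icpt + slope * xi)
    if (!is.na(slope_prev) &&
        abs(slope - slope_prev) <= tol * max(abs(slope_prev), 1e-300)) {
      stopped_by <- "tol"
      break
    }
    slope_prev <- slope
    if (iter >= max_iter) break
    # The residual scale is floored at half a time sample: peak times are
    # integer argmax positions, so smaller residuals are quantization, not
    # outliers (otherwise the pruning walks onto staircase plateaus).
    s_mad <- max(mad(resid), 0.5)
    drop_pt <- abs(resid) > 3 * s_mad
    if (!any(drop_pt)) { stopped_by <- "tol"; break }
    keep[keep][drop_pt] <- FALSE
  }
  xi <- x[keep]; ti <- t[keep]
  n <- length(xi)
  sst <- sum((ti - mean(ti))^2)
  ssr <- sum((ti - (icpt + slope * xi))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 1
  ok <- is.finite(slope) && slope > 0 && n >= 3 && stopped_by == "tol"
  vel <- if (is.finite(slope) && slope > 0) {
    px_per_sample_velocity(geometry) / slope
  } else {
    NA_real_
  }
  structure(
    list(velocity_mps = vel, intercept_sample = icpt, slope = slope,
         r_squared = r2, n_points = n, converged = ok,
         stopped_by = stopped_by, iterations = iter,
         depth_index = NA_integer_),
    class = "velocity_estimate"
  )
}

#' @export
print.velocity_estimate <- function(x, ...) {
  cat(sprintf("SAW velocity estimate: %.4g m/s (r2=%.4f, n=%d, %s)\n",
              x$velocity_mps, x$r_squared, x$n_points,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Depth-resolved SAW velocity profile
#'
#' Applies wavefront tracking and velocity fitting to each depth layer of
#' a filtered displacement field, from the surface downward, stopping after
#' `max_layers` (default 300) layers. A lateral window restricts the fit to
#' a lesion region when supplied. Layers that do not converge are recorded
#' but excluded from the summary.
#'
#' @param field a `displacement_field` from [displacement_pipeline()].
#' @param geometry a [scan_geometry()] (default: the field's own).
#' @param lateral_window optional `c(start_px, end_px)` fitting window.
#' @param max_layers maximum number of depth layers.
#' @param pulse_period_samples see [track_wavefront()].
#' @return a `depth_velocity_profile`: list with `estimates` (data.frame,
#'   one row per layer) and `summary` (mean, sd, n of converged layers).
#' @export
profile_volume <- function(field, geometry = NULL, lateral_window = NULL,
                           max_layers = 300, pulse_period_samples = NULL) {
  stopifnot(inherits(field, "displacement_field"))
  if (is.null(geometry)) geometry <- field$geometry
  nz <- min(dim(field$values)[1], max_layers)
  nt <- dim(field$values)[3]
  tw <- NULL
  if (!is.null(field$time_guard) && 2 * field$time_guard < nt - 2) {
    tw <- c(field$time_guard + 1L, nt - field$time_guard)
  }
  rows <- vector("list", nz)
  for (z in seq_len(nz)) {
    sl <- structure(
      list(values = field$values[z, , ], dead = field$dead[z, ],
           depth_index = z, filters_applied = field$filters_applied),
      class = "displacement_slice"
    )
    est <- tryCatch({
      tr <- track_wavefront(sl, lateral_window, pulse_period_samples,
                            time_window = tw)
      e <- fit_velocity(tr, geometry)
      e$depth_index <- z
      e
    }, error = function(e) {
      list(velocity_mps = NA_real_, intercept_sample = NA_real_,
           r_squared = NA_real_, n_points = 0L, converged = FALSE,
           stopped_by = conditionMessage(e), iterations = 0L,
           depth_index = z)
    })
    rows[[z]] <- data.frame(
      depth_index = z, velocity_mps = est$velocity_mps,
      r_squared = est$r_squared, n_points = est$n_points,
      converged = est$converged, stringsAsFactors = FALSE
    )
  }
  est_df <- do.call(rbind, rows)
  conv <- est_df$velocity_mps[est_df$converged]
  structure(
    list(estimates = est_df,
         summary = list(mean = if (length(conv)) mean(conv) else NA_real_,
                        sd = if (length(conv) > 1) sd(conv) else NA_real_,
                        n = length(conv))),
    class = "depth_velocity_profile"
  )
}

#' @export
print.depth_velocity_profile <- function(x, ...) {
  cat(sprintf(
    "Depth velocity profile: %d layers, %d converged, %.4g +/- %.3g m/s\n",
    nrow(x$estimates), x$summary$n, x$summary$mean,
    if (is.na(x$summary$sd)) 0 else x$summary$sd))
  invisible(x)
}
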