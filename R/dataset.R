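#' Build a labelled slice dataset from simulated acquisitions
#'
#' Simulates one volume per configuration, crops and normalizes it, and
#' emits one labelled slice per depth layer. Volumes (acquisitions) are
#' partitioned between the train/validation/test splits, so slices from a
#' single acquisition never appear in more than one split (preventing data
#' leakage). Labels are either the simulator's oracle velocity or the
#' time-of-flight estimate computed by the conventional pipeline.
#'
#' @param configs list of [sim_config()] objects, one per acquisition.
#'   Configs without a seed get a reproducible seed derived from `seed`.
#' @param split named fractions `c(train=, val=, test=)` summing to 1.
#' @param seed integer seed for volume simulation and split assignment.
#' @param labels `"oracle"` (true simulated velocity) or `"tof"`
#'   (time-of-flight estimate; slices whose layer did not converge are
#'   dropped).
#' @param slice_size lateral/time crop extent (the network input size).
#' @param lateral_offset,time_offset crop offsets, see [crop_volume()].
#' @param geometry a [scan_geometry()].
#' @param lateral_window optional TOF fitting window (lesion region),
#'   passed to [profile_volume()] when `labels = "tof"`.
#' @return an `oce_dataset`: list with `train`, `val`, `test`, each a list
#'   of `x` (array `[H, W, n]` of normalized slices), `y` (velocity
#'   labels, m/s), `id` (acquisition id per slice), `depth` (depth index
#'   per slice); plus `label_source` and the split assignment.
#' @export
make_dataset <- function(configs, split = c(train = 0.7, val = 0.15,
                                            test = 0.15),
                         seed = 1, labels = c("oracle", "tof"),
                         slice_size = 320, lateral_offset = 0,
                         time_offset = 0, geometry = scan_geometry(),
                         lateral_window = NULL) {
  labels <- match.arg(labels)
  if (length(configs) == 0) stop("empty config list")
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  if (any(split < 0) || length(split) != 3) {
    stop("split must be three non-negative fractions (train, val, test)")
  }
  n_vol <- length(configs)
  assign_split <- with_seed(seed, {
    counts <- diff(c(0, round(cumsum(split) * n_vol)))
    rep(c("train", "val", "test"), counts)[sample.int(n_vol)]
  })

  per_vol <- vector("list", n_vol)
  for (i in seq_len(n_vol)) {
    cfg <- configs[[i]]
    if (is.null(cfg$seed)) cfg$seed <- (seed * 1000L + i) %% .Machine$integer.max
    vol <- simulate_volume(cfg, geometry)
    vol <- crop_volume(vol, lateral_offset, time_offset, slice_size)
    x <- normalize_phase(vol$phase)
    nz <- dim(x)[1]
    y <- if (labels == "oracle") {
      rep(mean(vol$oracle_velocity$per_lateral[window_idx(lateral_window,
                                                          slice_size)]), nz)
    } else {
      period <- if (is.null(cfg$n_pulses) || cfg$n_pulses > 1) {
        round(geometry$aline_rate_hz / cfg$excitation_hz)
      }
      fld <- displacement_pipeline(vol, geometry)
      prof <- profile_volume(fld, geometry, lateral_window,
                             pulse_period_samples = period)
      ifelse(prof$estimates$converged, prof$estimates$velocity_mps, NA_real_)
    }
    keep <- !is.na(y)
    per_vol[[i]] <- list(x = x[keep, , , drop = FALSE], y = y[keep],
                         id = rep(i, sum(keep)),
                         depth = which(keep))
  }

  collect <- function(which_split) {
    sel <- which(assign_split == which_split)
    if (!length(sel)) {
      return(list(x = array(0, c(slice_size, slice_size, 0)),
                  y = numeric(0), id = integer(0), depth = integer(0)))
    }
    n_tot <- sum(vapply(per_vol[sel], function(p) length(p$y), 0L))
    x <- array(0, c(slice_size, slice_size, n_tot))
    y <- numeric(n_tot); id <- integer(n_tot); depth <- integer(n_tot)
    at <- 0L
    for (i in sel) {
      p <- per_vol[[i]]
      n_i <- length(p$y)
      if (n_i == 0) next
      for (j in seq_len(n_i)) x[, , at + j] <- p$x[j, , ]
      y[at + seq_len(n_i)] <- p$y
      id[at + seq_len(n_i)] <- p$id
      depth[at + seq_len(n_i)] <- p$depth
      at <- at + n_i
    }
    list(x = x, y = y, id = id, depth = depth)
  }
  structure(
    list(train = collect("train"), val = collect("val"),
         test = collect("test"), label_source = labels,
         split_assignment = assign_split, slice_size = slice_size),
    class = "oce_dataset"
  )
}

window_idx <- function(w, size) {
  if (is.null(w)) seq_len(size) else w[1]:w[2]
}

#' @export
print.oce_dataset <- function(x, ...) {
  cat(sprintf(
    "OCE slice dataset (%dx%d, labels=%s): train %d / val %d / test %d\n",
    x$slice_size, x$slice_size, x$label_source,
    length(x$train$y), length(x$val$y), length(x$test$y)))
  invisible(x)
}
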