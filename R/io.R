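#' Write an OCE volume container to disk
#'
#' Serializes the volume (phase array, scan-geometry attributes, optional
#' oracle velocity and simulation config) to a single-file RDS container.
#' The round trip through [read_volume()] is lossless.
#'
#' @param vol an `oce_volume` or bare `[depth, lateral, time]` array.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!inherits(vol, "oce_volume")) {
    stopifnot(is.array(vol), length(dim(vol)) == 3)
    vol <- structure(list(phase = vol, geometry = scan_geometry(),
                          oracle_velocity = NULL, config = NULL),
                     class = "oce_volume")
  }
  saveRDS(vol, path)
  invisible(path)
}

#' Read an OCE volume container
#'
#' Validates the container layout: `phase` must be a rank-3 array; missing
#' geometry attributes are filled with the system defaults, with a
#' warning naming each one.
#'
#' @param path file written by [write_volume()].
#' @return an `oce_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such volume file: ", path)
  v <- readRDS(path)
  if (!is.list(v) || is.null(v$phase)) {
    stop("malformed volume container: missing 'phase' dataset")
  }
  if (!is.array(v$phase) || length(dim(v$phase)) != 3) {
    stop(sprintf("malformed volume container: 'phase' must be rank 3, got rank %d",
                 length(dim(v$phase))))
  }
  defaults <- scan_geometry()
  g <- v$geometry
  if (is.null(g)) g <- list()
  for (f in names(unclass(defaults))) {
    if (is.null(g[[f]])) {
      warning("volume missing geometry attribute '", f,
              "'; using default ", unclass(defaults)[[f]], call. = FALSE)
      g[[f]] <- unclass(defaults)[[f]]
    }
  }
  v$geometry <- do.call(scan_geometry, g[names(unclass(defaults))])
  class(v) <- "oce_volume"
  v
}

# Write a data.frame artifact as CSV with the producing config hash
# embedded as a column.
write_artifact_csv <- function(df, path, hash) {
  df$config_hash <- hash
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: the simulated acquisitions,
#' crop/geometry settings, label source, network variant and training
#' recipe, and the output directory for stage artifacts.
#'
#' @param out_dir directory for stage artifacts (created if absent).
#' @param sim_configs list of [sim_config()], one per acquisition.
#' @param geometry a [scan_geometry()].
#' @param slice_size crop extent / network input size.
#' @param lateral_offset,time_offset crop offsets.
#' @param labels `"oracle"` or `"tof"` label source for training.
#' @param split train/val/test fractions.
#' @param variant VP-Net variant name.
#' @param train a [train_config()].
#' @param elasticity_mode aggregation mode for [modulus_report()].
#' @param seed master seed, propagated to every stochastic stage.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, sim_configs,
                            geometry = scan_geometry(),
                            slice_size = 48, lateral_offset = 0,
                            time_offset = 0, labels = "oracle",
                            split = c(train = 0.7, val = 0.15, test = 0.15),
                            variant = "S", train = train_config(),
                            elasticity_mode = "from-mean", seed = 1) {
  stopifnot(length(sim_configs) >= 1)
  structure(
    list(out_dir = out_dir, sim_configs = sim_configs, geometry = geometry,
         slice_size = slice_size, lateral_offset = lateral_offset,
         time_offset = time_offset, labels = labels, split = split,
         variant = variant, train = train,
         elasticity_mode = elasticity_mode, seed = seed),
    class = "pipeline_config"
  )
}

#' Run the full velocity-prediction pipeline
#'
#' Executes the stages in order: simulate -> preprocess -> wavefield ->
#' groundtruth -> train -> predict -> elasticity, writing one artifact per
#' stage under `cfg$out_dir` (volumes, slices, displacement fields,
#' `labels.csv`, `model.rds`, `pred.csv`, `moduli.csv`) plus a
#' `report.json` capturing versions, seeds, the config hash and stage
#' status. Stages are idempotent: an existing artifact is reused unless
#' `resume = FALSE`. A stage failure halts the run with the stage name.
#'
#' @param cfg a [pipeline_config()].
#' @param resume reuse existing stage artifacts (default `TRUE`).
#' @param verbose print stage progress.
#' @return list with the report (also written to `report.json`) and paths
#'   of all artifacts.
#' @export
run_pipeline <- function(cfg, resume = TRUE, verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg[setdiff(names(cfg), "out_dir")])
  paths <- list(
    volumes = file.path(cfg$out_dir, "volumes.rds"),
    slices = file.path(cfg$out_dir, "slices.rds"),
    disp = file.path(cfg$out_dir, "disp.rds"),
    labels = file.path(cfg$out_dir, "labels.csv"),
    model = file.path(cfg$out_dir, "model.rds"),
    pred = file.path(cfg$out_dir, "pred.csv"),
    moduli = file.path(cfg$out_dir, "moduli.csv"),
    report = file.path(cfg$out_dir, "report.json")
  )
  stages <- character()
  stage <- function(name, artifact, fn) {
    if (resume && file.exists(artifact)) {
      if (verbose) message("stage ", name, ": reusing ", artifact)
      stages <<- c(stages, name)
      return(invisible(NULL))
    }
    if (verbose) message("stage ", name, " ...")
    ok <- tryCatch({ fn(); TRUE }, error = function(e) e)
    if (!isTRUE(ok)) {
      stop(sprintf("pipeline stage '%s' failed (config %s): %s",
                   name, hash, conditionMessage(ok)), call. = FALSE)
    }
    stages <<- c(stages, name)
  }

  stage("simulate", paths$volumes, function() {
    vols <- vector("list", length(cfg$sim_configs))
    for (i in seq_along(cfg$sim_configs)) {
      sc <- cfg$sim_configs[[i]]
      if (is.null(sc$seed)) {
        sc$seed <- (cfg$seed * 1000L + i) %% .Machine$integer.max
      }
      vols[[i]] <- simulate_volume(sc, cfg$geometry)
    }
    saveRDS(vols, paths$volumes)
  })

  stage("preprocess", paths$slices, function() {
    vols <- readRDS(paths$volumes)
    slices <- lapply(vols, function(v) {
      vc <- crop_volume(v, cfg$lateral_offset, cfg$time_offset,
                        cfg$slice_size)
      list(x = normalize_phase(vc$phase),
           oracle = vc$oracle_velocity$per_lateral)
    })
    saveRDS(slices, paths$slices)
  })

  stage("wavefield", paths$disp, function() {
    vols <- readRDS(paths$volumes)
    fields <- lapply(vols, function(v) {
      vc <- crop_volume(v, cfg$lateral_offset, cfg$time_offset,
                        cfg$slice_size)
      displacement_pipeline(vc, cfg$geometry)
    })
    saveRDS(fields, paths$disp)
  })

  stage("groundtruth", paths$labels, function() {
    fields <- readRDS(paths$disp)
    rows <- lapply(seq_along(fields), function(i) {
      sc <- cfg$sim_configs[[i]]
      period <- if (is.null(sc$n_pulses) || sc$n_pulses > 1) {
        round(cfg$geometry$aline_rate_hz / sc$excitation_hz)
      }
      prof <- profile_volume(fields[[i]], cfg$geometry,
                             pulse_period_samples = period)
      cbind(volume = i, prof$estimates)
    })
    write_artifact_csv(do.call(rbind, rows), paths$labels, hash)
  })

  stage("train", paths$model, function() {
    ds <- dataset_from_artifacts(cfg, paths, hash)
    model <- build_vpnet(cfg$variant, input_size = cfg$slice_size,
                         seed = cfg$seed)
    tc <- cfg$train
    if (is.null(tc$seed)) tc$seed <- cfg$seed
    model <- train_vpnet(model, ds$train, ds$val, tc)
    saveRDS(list(model = model, dataset_split = ds$split_assignment),
            paths$model)
  })

  stage("predict", paths$pred, function() {
    if (!file.exists(paths$model)) {
      stop("missing checkpoint: ", paths$model)
    }
    mm <- readRDS(paths$model)
    ds <- dataset_from_artifacts(cfg, paths, hash)
    pred <- predict(mm$model, ds$test$x)
    write_artifact_csv(
      data.frame(volume = ds$test$id, depth_index = ds$test$depth,
                 label_mps = ds$test$y, pred_mps = pred),
      paths$pred, hash)
  })

  stage("elasticity", paths$moduli, function() {
    pr <- read.csv(paths$pred)
    rep_all <- modulus_report(pr$pred_mps, cfg$elasticity_mode)
    write_artifact_csv(
      data.frame(group = "test", mode = rep_all$mode, n = rep_all$n,
                 velocity_mean_mps = rep_all$velocity_mean,
                 velocity_sd_mps = rep_all$velocity_sd,
                 modulus_kpa = rep_all$modulus_kpa,
                 modulus_sd_kpa = rep_all$sd_kpa),
      paths$moduli, hash)
  })

  report <- list(
    package = "sawoce",
    version = as.character(utils::packageVersion("sawoce")),
    seed = cfg$seed, config_hash = hash, stages = stages,
    artifacts = lapply(paths[setdiff(names(paths), "report")], identity),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, pretty = TRUE)
  list(report = report, paths = paths)
}

# Rebuild the in-memory dataset from pipeline artifacts (slices + labels),
# with the same volume-level split assignment for a given seed.
dataset_from_artifacts <- function(cfg, paths, hash) {
  slices <- readRDS(paths$slices)
  n_vol <- length(slices)
  assign_split <- with_seed(cfg$seed, {
    counts <- diff(c(0, round(cumsum(cfg$split) * n_vol)))
    rep(c("train", "val", "test"), counts)[sample.int(n_vol)]
  })
  lab_df <- if (cfg$labels == "tof") read.csv(paths$labels)
  collect <- function(which_split) {
    sel <- which(assign_split == which_split)
    xs <- list(); ys <- numeric(); ids <- integer(); depths <- integer()
    for (i in sel) {
      x <- slices[[i]]$x
      nz <- dim(x)[1]
      y <- if (cfg$labels == "oracle") {
        rep(mean(slices[[i]]$oracle), nz)
      } else {
        li <- lab_df[lab_df$volume == i, ]
        ifelse(li$converged[seq_len(nz)], li$velocity_mps[seq_len(nz)],
               NA_real_)
      }
      keep <- which(!is.na(y))
      for (j in keep) xs[[length(xs) + 1]] <- x[j, , ]
      ys <- c(ys, y[keep]); ids <- c(ids, rep(i, length(keep)))
      depths <- c(depths, keep)
    }
    n <- length(xs)
    xa <- array(0, c(cfg$slice_size, cfg$slice_size, n))
    for (j in seq_len(n)) xa[, , j] <- xs[[j]]
    list(x = xa, y = ys, id = ids, depth = depths)
  }
  list(train = collect("train"), val = collect("val"),
       test = collect("test"), split_assignment = assign_split)
}
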