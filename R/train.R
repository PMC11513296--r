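#' Training configuration
#'
#' Defaults follow the velocity-regression recipe: Adam with learning rate
#' 1e-3, batch size 32, mean absolute error loss (squared error makes this
#' regression unstable), early stopping on validation MAE with patience 30
#' within at most `max_epochs` epochs.
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement); must be below `max_epochs`.
#' @param loss loss function; `"mae"` only.
#' @param seed integer seed for shuffling (weight init is seeded in
#'   [build_vpnet()]).
#' @return a `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 32,
                         max_epochs = 1000, patience = 30, loss = "mae",
                         seed = NULL) {
  loss <- match.arg(loss, "mae")
  stopifnot(learning_rate > 0, batch_size >= 2, max_epochs >= 1)
  if (patience >= max_epochs) stop("patience must be < max_epochs")
  structure(
    list(learning_rate = learning_rate, batch_size = batch_size,
         max_epochs = max_epochs, patience = patience, loss = loss,
         seed = seed),
    class = "train_config"
  )
}

# Adam moment update for one parameter tensor set.
adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train a VP-Net model
#'
#' Minimizes mean absolute error between predicted and label velocities
#' with Adam. After each epoch the validation MAE is computed (inference
#' mode, output clamped at 0); the weights of the best validation epoch
#' are kept and restored at the end, and training stops early once the
#' validation MAE has not improved for `patience` epochs. Training and
#' validation sets must come from disjoint acquisitions.
#'
#' @param model an untrained or trained `vpnet` from [build_vpnet()].
#' @param train_set,val_set lists with `x` (`[H, W, n]` slices), `y`
#'   (velocity labels) and optionally `id` (acquisition ids); the splits
#'   of [make_dataset()] fit directly.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return the trained `vpnet`, with a `history` data.frame (epoch,
#'   train_mae, val_mae), `best_epoch`, and the acquisition ids seen.
#' @export
train_vpnet <- function(model, train_set, val_set,
                        cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "vpnet"))
  n_tr <- length(train_set$y)
  if (n_tr == 0 || length(val_set$y) == 0) {
    stop("empty training or validation set")
  }
  if (!is.null(train_set$id) && !is.null(val_set$id) &&
      length(intersect(train_set$id, val_set$id)) > 0) {
    stop("training and validation sets share acquisition ids (data leakage)")
  }
  xtr <- as_batch(train_set$x)
  ytr <- train_set$y
  xval <- as_batch(val_set$x)

  opt <- lapply(model$layers, function(ly) {
    list(m = lapply(ly$params, function(p) p * 0),
         v = lapply(ly$params, function(p) p * 0))
  })
  t_step <- 0L
  best <- list(val = Inf, epoch = 0L, layers = NULL)
  hist <- vector("list", cfg$max_epochs)

  run <- function() {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n_tr)
      n_batch <- ceiling(n_tr / cfg$batch_size)
      tr_loss <- 0; tr_n <- 0L
      for (b in seq_len(n_batch)) {
        idx <- ord[((b - 1) * cfg$batch_size + 1):min(b * cfg$batch_size, n_tr)]
        if (length(idx) < 2) next   # batch norm needs >= 2 samples
        xb <- xtr[, , , idx, drop = FALSE]
        yb <- ytr[idx]
        fw <- model_forward(model, xb, training = TRUE, keep_cache = TRUE)
        if (any(!is.finite(fw$y))) {
          stop(sprintf("non-finite model output at epoch %d batch %d", epoch, b))
        }
        err <- fw$y - yb
        loss <- mean(abs(err))
        if (!is.finite(loss)) {
          stop(sprintf("non-finite loss at epoch %d batch %d", epoch, b))
        }
        tr_loss <- tr_loss + loss * length(idx); tr_n <- tr_n + length(idx)
        dY <- sign(err) / length(idx)
        bw <- model_backward(model, dY, fw$caches)
        t_step <<- t_step + 1L
        for (i in seq_along(model$layers)) {
          g <- bw$grads[[i]]
          if (is.null(g) || length(g) == 0) next
          r <- adam_step(model$layers[[i]]$params, g, opt[[i]],
                         cfg$learning_rate, t_step)
          model$layers[[i]]$params <<- r$params
          opt[[i]] <<- r$state
        }
        for (nm in names(fw$new_states)) {
          model$layers[[nm]]$state <<- fw$new_states[[nm]]
        }
      }
      val_pred <- pmax(model_forward(model, xval, training = FALSE)$y, 0)
      val_mae <- mean(abs(val_pred - val_set$y))
      hist[[epoch]] <<- data.frame(epoch = epoch, train_mae = tr_loss / tr_n,
                                   val_mae = val_mae)
      if (verbose) {
        message(sprintf("epoch %3d  train MAE %.4f  val MAE %.4f",
                        epoch, tr_loss / tr_n, val_mae))
      }
      if (val_mae < best$val) {   # ties keep the earlier epoch
        best <<- list(val = val_mae, epoch = epoch,
                      layers = model$layers)
      }
      if (epoch - best$epoch >= cfg$patience) break
    }
  }
  with_seed(cfg$seed, run())

  model$layers <- best$layers
  model$trained <- TRUE
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  model$best_epoch <- best$epoch
  model$best_val_mae <- best$val
  model$data_ids <- list(train = unique(train_set$id),
                         val = unique(val_set$id))
  model
}

#' Evaluate a trained model on a held-out test set
#'
#' Computes per-slice squared and absolute errors between predicted and
#' label velocities, with grouped mean +/- standard deviation summaries
#' and the predicted-velocity mean +/- sd per group. Test acquisitions
#' must be disjoint from those seen during training and validation; the
#' overlap check is part of the precondition.
#'
#' @param model a trained `vpnet`.
#' @param test_set list with `x`, `y` and optionally `id` (as produced by
#'   [make_dataset()]).
#' @param groups optional factor/vector of group labels per test slice
#'   (e.g. material or skin site); default one group.
#' @return an `eval_report`: list with `per_slice` (data.frame of label,
#'   prediction, mse, mae per slice) and `groups` (data.frame of grouped
#'   mean +/- sd of mse, mae and predicted velocity).
#' @export
evaluate_model <- function(model, test_set, groups = NULL) {
  stopifnot(inherits(model, "vpnet"))
  n <- length(test_set$y)
  if (n == 0) stop("empty test set")
  if (!is.null(model$data_ids) && !is.null(test_set$id)) {
    seen <- unlist(model$data_ids)
    if (length(intersect(test_set$id, seen)) > 0) {
      stop("test set shares acquisition ids with training/validation ",
           "(data leakage)")
    }
  }
  if (is.null(groups)) groups <- rep("all", n)
  if (length(groups) != n) stop("groups must have one entry per test slice")
  if (!is.factor(groups)) groups <- factor(groups)
  if (any(table(groups) == 0)) {
    stop("group with zero slices: ",
         paste(levels(groups)[table(groups) == 0], collapse = ", "))
  }
  pred <- predict(model, test_set$x)
  per_slice <- data.frame(
    id = if (is.null(test_set$id)) NA_integer_ else test_set$id,
    group = groups, label = test_set$y, pred = pred,
    mse = (test_set$y - pred)^2, mae = abs(test_set$y - pred))
  agg <- function(v) c(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0)
  gs <- lapply(levels(groups), function(g) {
    s <- per_slice[per_slice$group == g, ]
    data.frame(group = g, n = nrow(s),
               mse_mean = mean(s$mse), mse_sd = agg(s$mse)[["sd"]],
               mae_mean = mean(s$mae), mae_sd = agg(s$mae)[["sd"]],
               pred_mean = mean(s$pred), pred_sd = agg(s$pred)[["sd"]],
               label_mean = mean(s$label), stringsAsFactors = FALSE)
  })
  structure(list(per_slice = per_slice, groups = do.call(rbind, gs)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Velocity prediction evaluation\n")
  g <- x$groups
  for (i in seq_len(nrow(g))) {
    cat(sprintf(
      "  %s (n=%d): MAE %.3f +/- %.3f, MSE %.3f +/- %.3f, pred %.2f +/- %.2f m/s\n",
      g$group[i], g$n[i], g$mae_mean[i], g$mae_sd[i], g$mse_mean[i],
      g$mse_sd[i], g$pred_mean[i], g$pred_sd[i]))
  }
  invisible(x)
}
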