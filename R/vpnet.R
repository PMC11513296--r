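#' VP-Net size variant
#'
#' Filter-count schedules of the three network sizes: the five CBR
#' (convolution - batch norm - ReLU) blocks and the three separable
#' convolution blocks.
#'
#' * S: CBR \{16, 16, 16, 32, 64\}, separable \{16, 32, 64\}
#' * B: CBR \{16, 16, 32, 64, 128\}, separable \{32, 64, 128\}
#' * L: CBR \{32, 32, 64, 128, 256\}, separable \{64, 128, 256\}
#'
#' @param name `"S"`, `"B"` or `"L"`.
#' @return list with `name`, `fs_cbr` (length 5), `fs_scb` (length 3).
#' @export
vpnet_variant <- function(name = c("B", "S", "L")) {
  name <- match.arg(name)
  schedules <- list(
    S = list(fs_cbr = c(16, 16, 16, 32, 64), fs_scb = c(16, 32, 64)),
    B = list(fs_cbr = c(16, 16, 32, 64, 128), fs_scb = c(32, 64, 128)),
    L = list(fs_cbr = c(32, 32, 64, 128, 256), fs_scb = c(64, 128, 256))
  )
  c(list(name = name), schedules[[name]])
}

#' Build a VP-Net velocity regression model
#'
#' Assembles the network: CBR1(k=11, s=4) -> CBR2(3, 1) -> CBR3(7, 2) ->
#' separable + SE -> CBR4(7, 2) -> separable + SE -> CBR5(3, 1) ->
#' separable + SE -> global average pooling -> dense(1). Each separable
#' block (depthwise 3x3 + pointwise 1x1, both batch-normalized with ReLU)
#' and its SE (squeeze-and-excitation) gate preserve the channel count of
#' the preceding CBR block, which is the only arrangement consistent with
#' the filter schedules of [vpnet_variant()]. "Same" padding keeps the
#' stride arithmetic exact (320 -> 80 -> 80 -> 40 -> 20 -> 20 spatial).
#' The model outputs one scalar per input slice; at inference the output
#' is clamped at 0 (velocities are non-negative).
#'
#' @param variant a [vpnet_variant()] or a variant name.
#' @param input_size spatial extent of the (square) input slice. The
#'   full-scale input is 320; smaller inputs (e.g. 48) preserve the
#'   architecture for desk-scale training.
#' @param in_channels input channel count (1 for phase slices).
#' @param seed integer seed for weight initialization (Glorot uniform).
#' @return an object of class `vpnet`.
#' @examples
#' m <- build_vpnet("S", input_size = 48, seed = 1)
#' summary(m)$parameter_count
#' @export
build_vpnet <- function(variant = vpnet_variant("B"), input_size = 320,
                        in_channels = 1, seed = NULL) {
  if (is.character(variant)) variant <- vpnet_variant(variant)
  fc <- variant$fs_cbr
  fs <- variant$fs_scb
  if (length(fc) != 5 || length(fs) != 3) {
    stop("variant needs 5 CBR and 3 separable filter counts")
  }
  if (!all(fs == fc[3:5])) {
    stop("separable block filters must match the preceding CBR filters (",
         paste(fc[3:5], collapse = ", "), ")")
  }
  cbr <- function(tag, k, s, in_c, out_c) {
    list(layer_conv(paste0(tag, "_conv"), k, s, in_c, out_c),
         layer_bn(paste0(tag, "_bn"), out_c),
         layer_relu(paste0(tag, "_relu")))
  }
  sep <- function(tag, C) {
    list(layer_dwconv(paste0(tag, "_dw"), C),
         layer_bn(paste0(tag, "_dw_bn"), C),
         layer_relu(paste0(tag, "_dw_relu")),
         layer_pwconv(paste0(tag, "_pw"), C, C),
         layer_bn(paste0(tag, "_pw_bn"), C),
         layer_relu(paste0(tag, "_pw_relu")))
  }
  layers <- with_seed(seed, c(
    cbr("cbr1", 11, 4, in_channels, fc[1]),
    cbr("cbr2", 3, 1, fc[1], fc[2]),
    cbr("cbr3", 7, 2, fc[2], fc[3]),
    sep("sep1", fs[1]), list(layer_se("se1", fs[1])),
    cbr("cbr4", 7, 2, fc[3], fc[4]),
    sep("sep2", fs[2]), list(layer_se("se2", fs[2])),
    cbr("cbr5", 3, 1, fc[4], fc[5]),
    sep("sep3", fs[3]), list(layer_se("se3", fs[3])),
    list(layer_gap("gap"), layer_dense("head", fc[5], 1))
  ))
  names(layers) <- vapply(layers, `[[`, "", "name")
  structure(
    list(layers = layers, variant = variant, input_size = input_size,
         in_channels = in_channels, trained = FALSE, data_ids = NULL),
    class = "vpnet"
  )
}

# Forward pass through the whole network. Returns the scalar outputs (one
# per slice) and, when `keep_cache`, the per-layer caches and activations
# needed by backprop / Grad-CAM.
model_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  stopifnot(is.array(x), length(dim(x)) == 4)
  caches <- if (keep_cache) vector("list", length(model$layers))
  acts <- if (keep_cache) vector("list", length(model$layers))
  new_states <- list()
  h <- x
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    r <- layer_forward(ly, h, training = training)
    h <- r$out
    if (keep_cache) {
      caches[[i]] <- r$cache
      acts[[i]] <- h
    }
    if (training && !is.null(r$state)) new_states[[ly$name]] <- r$state
  }
  list(y = as.vector(h), caches = caches, acts = acts,
       new_states = new_states)
}

# Backward pass. `dY` is the gradient of the objective with respect to the
# scalar outputs (length N). Returns per-layer parameter gradients; if
# `probe` names a layer, also the gradient with respect to that layer's
# output activation (used by Grad-CAM), computed by stopping there.
model_backward <- function(model, dY, caches, probe = NULL) {
  n_l <- length(model$layers)
  grads <- vector("list", n_l)
  names(grads) <- names(model$layers)
  dh <- matrix(dY, nrow = 1)
  probe_grad <- NULL
  for (i in rev(seq_len(n_l))) {
    ly <- model$layers[[i]]
    if (!is.null(probe) && ly$name == probe) {
      probe_grad <- dh
      break
    }
    r <- layer_backward(ly, dh, caches[[i]])
    grads[[i]] <- r$grads
    dh <- r$dx
  }
  list(grads = grads, probe_grad = probe_grad)
}

#' Predict SAW velocities for a batch of slices
#'
#' @param object a `vpnet` model.
#' @param x normalized slices: array `[H, W, N]` or `[H, W, 1, N]`, or a
#'   single `[H, W]` matrix, values in \eqn{[0, 1]}.
#' @param clamp clamp predictions at 0 (velocity is non-negative); default
#'   `TRUE`.
#' @param ... unused.
#' @return numeric vector of predicted velocities, m/s.
#' @export
predict.vpnet <- function(object, x, clamp = TRUE, ...) {
  x <- as_batch(x)
  y <- model_forward(object, x, training = FALSE)$y
  if (clamp) y <- pmax(y, 0)
  y
}

# Coerce slices to the [H, W, C, N] batch layout.
as_batch <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1, 1))
  else if (length(dim(x)) == 3) {
    d <- dim(x)
    x <- array(x, c(d[1], d[2], 1, d[3]))
  }
  stopifnot(length(dim(x)) == 4)
  x
}

#' Model summary: layer table, parameters and FLOPs
#'
#' Deterministic per-layer and total counts of trainable parameters and
#' multiply-add operations (MACs) at the model's input size. Convolutional
#' MACs are `outH * outW * k^2 * Cin * Cout`; batch-norm, SE and pooling
#' contributions are counted elementwise.
#'
#' @param object a `vpnet` model.
#' @param ... unused.
#' @return a `vpnet_summary`: list with `parameter_count`, `flops` and a
#'   `layer_table` data.frame (name, type, output shape, params, flops).
#' @export
summary.vpnet <- function(object, ...) {
  shp <- c(object$input_size, object$input_size, object$in_channels)
  rows <- vector("list", length(object$layers))
  for (i in seq_along(object$layers)) {
    ly <- object$layers[[i]]
    out_shp <- layer_out_shape(ly, shp)
    cost <- layer_cost(ly, shp, out_shp)
    rows[[i]] <- data.frame(
      name = ly$name, type = ly$type,
      out_h = out_shp[1], out_w = out_shp[2], out_c = out_shp[3],
      params = cost$params, flops = cost$flops, stringsAsFactors = FALSE)
    shp <- out_shp
  }
  tab <- do.call(rbind, rows)
  structure(
    list(parameter_count = sum(tab$params), flops = sum(tab$flops),
         layer_table = tab, variant = object$variant$name,
         input_size = object$input_size),
    class = "vpnet_summary"
  )
}

#' @export
print.vpnet_summary <- function(x, ...) {
  cat(sprintf("VP-Net-%s @ %dx%d input\n", x$variant, x$input_size,
              x$input_size))
  print(x$layer_table, row.names = FALSE)
  cat(sprintf("total parameters: %s\ntotal MACs: %s\n",
              format(x$parameter_count, big.mark = ","),
              format(x$flops, big.mark = ",")))
  invisible(x)
}

#' @export
print.vpnet <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("VP-Net-%s (%dx%d input, %s parameters, %s)\n",
              x$variant$name, x$input_size, x$input_size,
              format(s$parameter_count, big.mark = ","),
              if (isTRUE(x$trained)) "trained" else "untrained"))
  invisible(x)
}
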