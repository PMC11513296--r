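#' Grad-CAM for the scalar velocity output
#'
#' Gradient-weighted class activation mapping adapted to regression: the
#' differentiated quantity is the model-predicted SAW velocity itself
#' rather than a class score. For the probed activation `A` (channels
#' `k`), channel weights are the spatial means of `dv/dA_k`; the map is
#' `ReLU(sum_k w_k A_k)`, min-max normalized to `[0, 1]`, and bilinearly
#' upsampled to the input extent for the overlay.
#'
#' Probes address the first convolution of a CBR block, either by layer
#' name (`"cbr1_conv"`, `"cbr3_conv"`, `"cbr4_conv"`, `"cbr5_conv"`) or by
#' the ordinal of the 2-D (non-depthwise) convolution layer in the
#' network (1, 3, 5, 7 correspond to the four CBR probes above, with
#' pointwise convolutions counted in between).
#'
#' @param model a `vpnet`.
#' @param slice one normalized slice: `[H, W]` matrix in \eqn{[0, 1]}.
#' @param probe layer name or 2-D convolution ordinal.
#' @return a `gradcam_map`: list with `heatmap` (probed resolution,
#'   non-negative, normalized), `overlay` (input resolution), `raw`
#'   (pre-normalization map), `probed_layer`, `prediction`.
#' @export
grad_cam <- function(model, slice, probe = "cbr1_conv") {
  stopifnot(inherits(model, "vpnet"), is.matrix(slice))
  probe <- resolve_probe(model, probe)
  x <- as_batch(slice)
  fw <- model_forward(model, x, training = FALSE, keep_cache = TRUE)
  i_probe <- match(probe, names(model$layers))
  A <- fw$acts[[i_probe]]
  bw <- model_backward(model, 1, fw$caches, probe = probe)
  dA <- bw$probe_grad
  d <- dim(A)
  hw <- d[1] * d[2]
  w_k <- colSums(matrix(dA, hw, d[3])) / hw         # spatial mean per channel
  raw <- matrix(matrix(A, hw, d[3]) %*% w_k, d[1], d[2])
  raw <- pmax(raw, 0)
  rng <- range(raw)
  heat <- if (rng[2] > rng[1]) (raw - rng[1]) / (rng[2] - rng[1]) else raw * 0
  overlay <- resize_bilinear(heat, nrow(slice), ncol(slice))
  structure(
    list(heatmap = heat, overlay = overlay, raw = raw,
         probed_layer = probe, prediction = max(fw$y, 0)),
    class = "gradcam_map"
  )
}

# Map a probe given as a conv ordinal (counting 2-D convolutions: CBR and
# pointwise, not depthwise) or layer name to a layer name.
resolve_probe <- function(model, probe) {
  conv2d <- names(model$layers)[vapply(model$layers, function(l)
    l$type %in% c("conv", "pwconv"), TRUE)]
  if (is.numeric(probe)) {
    if (probe < 1 || probe > length(conv2d)) {
      stop("probe not found: conv ordinal ", probe, " of ",
           length(conv2d))
    }
    return(conv2d[probe])
  }
  if (!probe %in% names(model$layers)) {
    stop("probe not found: no layer named '", probe, "'")
  }
  probe
}

# Bilinear image resize (align-corners convention).
resize_bilinear <- function(m, H, W) {
  h0 <- nrow(m); w0 <- ncol(m)
  ri <- if (H == 1) rep(1, H) else seq(1, h0, length.out = H)
  ci <- if (W == 1) rep(1, W) else seq(1, w0, length.out = W)
  rlo <- pmin(floor(ri), h0); rhi <- pmin(rlo + 1, h0); rf <- ri - rlo
  clo <- pmin(floor(ci), w0); chi <- pmin(clo + 1, w0); cf <- ci - clo
  a <- m[rlo, clo, drop = FALSE] * outer(1 - rf, 1 - cf)
  b <- m[rhi, clo, drop = FALSE] * outer(rf, 1 - cf)
  cc <- m[rlo, chi, drop = FALSE] * outer(1 - rf, cf)
  dd <- m[rhi, chi, drop = FALSE] * outer(rf, cf)
  a + b + cc + dd
}
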