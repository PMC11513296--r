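# Minimal CNN layer engine used by the VP-Net regression model.
#
# Feature maps are numeric arrays [H, W, C, N] (column-major). Every layer
# is a plain list with a `type`, a `name`, trainable `params`, and (for
# batch norm) running `state`. `layer_forward()` returns the output plus a
# cache; `layer_backward()` consumes the cache and returns the input
# gradient and per-parameter gradients. All backward passes are checked
# against finite differences in the test suite.

glorot_uniform <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dims)
}

layer_conv <- function(name, k, stride, in_c, out_c) {
  list(type = "conv", name = name, k = k, stride = stride,
       in_c = in_c, out_c = out_c,
       params = list(W = glorot_uniform(k * k * in_c, k * k * out_c,
                                        c(k, k, in_c, out_c)),
                     b = numeric(out_c)))
}

layer_bn <- function(name, C, momentum = 0.9, eps = 1e-3) {
  list(type = "bn", name = name, C = C, momentum = momentum, eps = eps,
       params = list(gamma = rep(1, C), beta = numeric(C)),
       state = list(rm = numeric(C), rv = rep(1, C)))
}

layer_relu <- function(name) list(type = "relu", name = name, params = list())

layer_dwconv <- function(name, C, k = 3) {
  list(type = "dwconv", name = name, C = C, k = k,
       params = list(W = glorot_uniform(k * k, k * k, c(k, k, C)),
                     b = numeric(C)))
}

layer_pwconv <- function(name, in_c, out_c) {
  list(type = "pwconv", name = name, in_c = in_c, out_c = out_c,
       params = list(W = glorot_uniform(in_c, out_c, c(in_c, out_c)),
                     b = numeric(out_c)))
}

layer_se <- function(name, C, reduction = 4) {
  if (C %% reduction != 0) {
    stop(sprintf("SE block: channel count %d not divisible by %d",
                 C, reduction))
  }
  Cr <- C %/% reduction
  list(type = "se", name = name, C = C, Cr = Cr,
       params = list(W1 = glorot_uniform(C, Cr, c(C, Cr)), b1 = numeric(Cr),
                     W2 = glorot_uniform(Cr, C, c(Cr, C)), b2 = numeric(C)))
}

layer_gap <- function(name) list(type = "gap", name = name, params = list())

layer_dense <- function(name, in_d, out_d) {
  list(type = "dense", name = name, in_d = in_d, out_d = out_d,
       params = list(W = glorot_uniform(in_d, out_d, c(in_d, out_d)),
                     b = numeric(out_d)))
}

# "same" padding amounts for a given extent/kernel/stride (excess padding
# goes to the bottom/right).
same_pad <- function(n, k, stride) {
  out <- ceiling(n / stride)
  p <- max((out - 1) * stride + k - n, 0)
  list(out = out, beg = p %/% 2)
}

# Per-channel broadcasts and reductions over [H, W, C, N] arrays are done
# by the fused C++ helpers (channel_affine_cpp etc.) for speed.

layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv = {
      d <- dim(x)
      ph <- same_pad(d[1], layer$k, layer$stride)
      pw <- same_pad(d[2], layer$k, layer$stride)
      X <- im2col_cpp(x, d[1], d[2], d[3], d[4], layer$k, layer$stride,
                      ph$beg, pw$beg, ph$out, pw$out)
      Wm <- layer$params$W
      dim(Wm) <- c(layer$k^2 * layer$in_c, layer$out_c)
      Y <- X %*% Wm
      Y <- Y + rep(layer$params$b, each = nrow(Y))
      dim(Y) <- c(ph$out, pw$out, d[4], layer$out_c)
      out <- aperm(Y, c(1, 2, 4, 3))
      list(out = out, cache = list(X = X, dims = d, outH = ph$out,
                                   outW = pw$out, padT = ph$beg,
                                   padL = pw$beg))
    },
    bn = {
      d <- dim(x)
      hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
      m_per <- hw * N
      if (training) {
        mu <- channel_sums_cpp(x, hw, C, N) / m_per
        va <- channel_dot_cpp(x, x, hw, C, N) / m_per - mu^2
        va <- pmax(va, 0)
        inv_std <- 1 / sqrt(va + layer$eps)
        xhat <- channel_affine_cpp(x, inv_std, -mu * inv_std, hw, C, N)
        state <- list(
          rm = layer$momentum * layer$state$rm + (1 - layer$momentum) * mu,
          rv = layer$momentum * layer$state$rv + (1 - layer$momentum) * va)
      } else {
        inv_std <- 1 / sqrt(layer$state$rv + layer$eps)
        xhat <- channel_affine_cpp(x, inv_std, -layer$state$rm * inv_std,
                                   hw, C, N)
        state <- NULL
      }
      out <- channel_affine_cpp(xhat, layer$params$gamma,
                                layer$params$beta, hw, C, N)
      dim(out) <- d
      dim(xhat) <- d
      list(out = out,
           cache = list(xhat = xhat, inv_std = inv_std, dims = d,
                        training = training),
           state = state)
    },
    relu = list(out = pmax(x, 0), cache = list(mask = x > 0)),
    dwconv = {
      d <- dim(x)
      out <- depthwise_forward_cpp(x, d[1], d[2], d[3], d[4],
                                   layer$params$W, layer$params$b, layer$k)
      list(out = out, cache = list(x = x, dims = d))
    },
    pwconv = {
      d <- dim(x)
      Xm <- aperm(x, c(1, 2, 4, 3))
      dim(Xm) <- c(d[1] * d[2] * d[4], d[3])
      Y <- Xm %*% layer$params$W
      Y <- Y + rep(layer$params$b, each = nrow(Y))
      dim(Y) <- c(d[1], d[2], d[4], layer$out_c)
      list(out = aperm(Y, c(1, 2, 4, 3)), cache = list(Xm = Xm, dims = d))
    },
    se = {
      d <- dim(x)
      hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
      S <- matrix(cn_sums_cpp(x, hw) / hw, C, N)
      z1 <- crossprod(layer$params$W1, S) + layer$params$b1
      a1 <- pmax(z1, 0)
      z2 <- crossprod(layer$params$W2, a1) + layer$params$b2
      g <- 1 / (1 + exp(-z2))
      out <- cn_scale_cpp(x, g, hw)
      dim(out) <- d
      list(out = out, cache = list(x = x, S = S, z1 = z1, a1 = a1, g = g,
                                   dims = d))
    },
    gap = {
      d <- dim(x)
      hw <- d[1] * d[2]
      S <- matrix(cn_sums_cpp(x, hw) / hw, d[3], d[4])
      list(out = S, cache = list(dims = d))
    },
    dense = {
      y <- crossprod(layer$params$W, x) + layer$params$b
      list(out = y, cache = list(x = x))
    },
    stop("unknown layer type: ", layer$type)
  )
}

layer_backward <- function(layer, dout, cache) {
  switch(layer$type,
    conv = {
      k <- layer$k
      dYm <- aperm(dout, c(1, 2, 4, 3))
      dim(dYm) <- c(cache$outH * cache$outW * cache$dims[4], layer$out_c)
      dW <- crossprod(cache$X, dYm)
      dim(dW) <- c(k, k, layer$in_c, layer$out_c)
      db <- colSums(dYm)
      Wm <- layer$params$W
      dim(Wm) <- c(k^2 * layer$in_c, layer$out_c)
      dXc <- tcrossprod(dYm, Wm)
      d <- cache$dims
      dx <- col2im_cpp(dXc, d[1], d[2], d[3], d[4], k, layer$stride,
                       cache$padT, cache$padL, cache$outH, cache$outW)
      list(dx = dx, grads = list(W = dW, b = db))
    },
    bn = {
      d <- cache$dims
      hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
      dgamma <- channel_dot_cpp(dout, cache$xhat, hw, C, N)
      dbeta <- channel_sums_cpp(dout, hw, C, N)
      g_is <- layer$params$gamma * cache$inv_std
      if (cache$training) {
        m_per <- hw * N
        # dx = g_is*dout - (g_is/m)*dbeta - xhat*(g_is/m)*dgamma
        dx <- channel_affine2_cpp(dout, cache$xhat, g_is,
                                  -g_is * dbeta / m_per,
                                  -g_is * dgamma / m_per, hw, C, N)
      } else {
        dx <- channel_affine_cpp(dout, g_is, numeric(C), hw, C, N)
      }
      dim(dx) <- d
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = list(dx = dout * cache$mask, grads = list()),
    dwconv = {
      d <- cache$dims
      r <- depthwise_backward_cpp(cache$x, layer$params$W, dout,
                                  d[1], d[2], d[3], d[4], layer$k)
      list(dx = r$dx, grads = list(W = r$dw, b = r$db))
    },
    pwconv = {
      d <- cache$dims
      dYm <- aperm(dout, c(1, 2, 4, 3))
      dim(dYm) <- c(d[1] * d[2] * d[4], layer$out_c)
      dW <- crossprod(cache$Xm, dYm)
      db <- colSums(dYm)
      dXm <- tcrossprod(dYm, layer$params$W)
      dim(dXm) <- c(d[1], d[2], d[4], d[3])
      list(dx = aperm(dXm, c(1, 2, 4, 3)), grads = list(W = dW, b = db))
    },
    se = {
      d <- cache$dims
      hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
      g <- cache$g
      dg <- matrix(cn_dots_cpp(dout, cache$x, hw), C, N)
      dz2 <- dg * g * (1 - g)
      dW2 <- tcrossprod(cache$a1, dz2)
      db2 <- rowSums(dz2)
      da1 <- layer$params$W2 %*% dz2
      dz1 <- da1 * (cache$z1 > 0)
      dW1 <- tcrossprod(cache$S, dz1)
      db1 <- rowSums(dz1)
      dS <- layer$params$W1 %*% dz1
      dx <- cn_scale_add_cpp(dout, g, dS / hw, hw)
      dim(dx) <- d
      list(dx = dx, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
    },
    gap = {
      d <- cache$dims
      hw <- d[1] * d[2]
      dx <- rep(as.vector(dout) / hw, each = hw)
      dim(dx) <- d
      list(dx = dx, grads = list())
    },
    dense = {
      dW <- tcrossprod(cache$x, dout)
      db <- rowSums(dout)
      dx <- layer$params$W %*% dout
      list(dx = dx, grads = list(W = dW, b = db))
    },
    stop("unknown layer type: ", layer$type)
  )
}

# Output spatial/channel shape of a layer given its input shape c(H, W, C).
layer_out_shape <- function(layer, shp) {
  switch(layer$type,
    conv = c(ceiling(shp[1] / layer$stride), ceiling(shp[2] / layer$stride),
             layer$out_c),
    pwconv = c(shp[1], shp[2], layer$out_c),
    gap = c(1, 1, shp[3]),
    dense = c(1, 1, layer$out_d),
    shp
  )
}

# Trainable parameter count and multiply-add (MAC) count of one layer.
layer_cost <- function(layer, in_shp, out_shp) {
  hw_out <- out_shp[1] * out_shp[2]
  switch(layer$type,
    conv = list(params = layer$k^2 * layer$in_c * layer$out_c + layer$out_c,
                flops = hw_out * layer$out_c * layer$k^2 * layer$in_c),
    bn = list(params = 2 * layer$C, flops = 2 * hw_out * out_shp[3]),
    relu = list(params = 0, flops = 0),
    dwconv = list(params = layer$k^2 * layer$C + layer$C,
                  flops = hw_out * layer$C * layer$k^2),
    pwconv = list(params = layer$in_c * layer$out_c + layer$out_c,
                  flops = hw_out * layer$in_c * layer$out_c),
    se = list(params = layer$C * layer$Cr * 2 + layer$Cr + layer$C,
              flops = layer$C * layer$Cr * 2 +
                in_shp[1] * in_shp[2] * layer$C * 2),
    gap = list(params = 0, flops = in_shp[1] * in_shp[2] * in_shp[3]),
    dense = list(params = layer$in_d * layer$out_d + layer$out_d,
                 flops = layer$in_d * layer$out_d),
    list(params = 0, flops = 0)
  )
}
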