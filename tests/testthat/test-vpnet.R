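ns <- asNamespace("sawoce")

test_that("variant filter schedules match the S/B/L definitions", {
  expect_equal(vpnet_variant("S")$fs_cbr, c(16, 16, 16, 32, 64))
  expect_equal(vpnet_variant("S")$fs_scb, c(16, 32, 64))
  expect_equal(vpnet_variant("B")$fs_cbr, c(16, 16, 32, 64, 128))
  expect_equal(vpnet_variant("L")$fs_scb, c(64, 128, 256))
  bad <- list(name = "X", fs_cbr = c(16, 16, 32, 64, 128),
              fs_scb = c(16, 64, 128))
  expect_error(build_vpnet(bad), "must match")
})

test_that("feature-map shapes propagate with same padding", {
  m <- build_vpnet("S", input_size = 48, seed = 1)
  x <- array(runif(48 * 48), c(48, 48, 1, 1))
  fw <- ns$model_forward(m, x, keep_cache = TRUE)
  acts <- fw$acts
  names(acts) <- names(m$layers)
  shp <- lapply(acts, dim)
  expect_equal(shp$cbr1_relu, c(12, 12, 16, 1))  # 48 / 4
  expect_equal(shp$cbr2_relu, c(12, 12, 16, 1))  # stride 1 preserves
  expect_equal(shp$cbr3_relu, c(6, 6, 16, 1))    # 12 / 2
  expect_equal(shp$sep1_pw_relu, c(6, 6, 16, 1)) # separable preserves
  expect_equal(shp$cbr4_relu, c(3, 3, 32, 1))
  expect_equal(shp$cbr5_relu, c(3, 3, 64, 1))
  expect_equal(dim(acts$gap), c(64, 1))
  expect_length(fw$y, 1)
})

test_that("parameter and FLOP counts are deterministic and ordered S < B < L", {
  s1 <- summary(build_vpnet("B", input_size = 320, seed = 1))
  s2 <- summary(build_vpnet("B", input_size = 320, seed = 99))
  expect_identical(s1$parameter_count, s2$parameter_count)
  expect_identical(s1$flops, s2$flops)

  sums <- lapply(c("S", "B", "L"), function(v)
    summary(build_vpnet(v, input_size = 320, seed = 1)))
  p <- vapply(sums, `[[`, 0, "parameter_count")
  f <- vapply(sums, `[[`, 0, "flops")
  expect_true(p[1] < p[2] && p[2] < p[3])
  expect_true(f[1] < f[2] && f[2] < f[3])
})

test_that("separable blocks cost C*9 + C^2 weights, less than a full 3x3 conv", {
  m <- build_vpnet("B", input_size = 48, seed = 1)
  tab <- summary(m)$layer_table
  C <- 128
  dw <- tab$params[tab$name == "sep3_dw"]
  pw <- tab$params[tab$name == "sep3_pw"]
  expect_equal(dw, 9 * C + C)        # depthwise weights + bias
  expect_equal(pw, C * C + C)        # pointwise weights + bias
  full_conv <- 9 * C * C + C
  expect_lt(dw + pw, full_conv)
})

test_that("SE blocks gate channels in (0, 1) and reduce to identity when saturated", {
  ly <- ns$layer_se("se", 8)
  x <- array(rnorm(5 * 5 * 8 * 2), c(5, 5, 8, 2))
  out <- ns$layer_forward(ly, x)$out
  ratio <- out / x
  expect_true(all(ratio > 0 & ratio < 1))

  ly$params$W1[] <- 0; ly$params$W2[] <- 0
  ly$params$b2[] <- 30                      # sigmoid(30) ~ 1: identity gate
  expect_equal(ns$layer_forward(ly, x)$out, x, tolerance = 1e-10)

  expect_error(ns$layer_se("se", 6), "not divisible")
})

test_that("global average pooling of a constant map returns that constant", {
  x <- array(3.25, c(4, 6, 3, 2))
  S <- ns$layer_forward(ns$layer_gap("gap"), x)$out
  expect_equal(S, matrix(3.25, 3, 2))
})

test_that("a CBR block maps zero input to zero output at initialization", {
  m <- build_vpnet("S", input_size = 16, seed = 2)
  x <- array(0, c(16, 16, 1, 1))
  fw <- ns$model_forward(m, x, training = FALSE, keep_cache = TRUE)
  acts <- fw$acts
  names(acts) <- names(m$layers)
  expect_equal(max(abs(acts$cbr1_relu)), 0)
  expect_true(is.finite(fw$y))
})

test_that("predictions are finite, non-negative scalars for all variants", {
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  for (v in c("S", "B", "L")) {
    m <- build_vpnet(v, input_size = 32, seed = 4)
    p <- predict(m, x)
    expect_length(p, 3)
    expect_true(all(is.finite(p)) && all(p >= 0))
  }
})

test_that("permuting the batch permutes predictions identically", {
  m <- build_vpnet("S", input_size = 24, seed = 5)
  x <- array(runif(24 * 24 * 6), c(24, 24, 6))
  p <- predict(m, x)
  perm <- c(4, 1, 6, 2, 5, 3)
  expect_equal(predict(m, x[, , perm]), p[perm], tolerance = 1e-12)
})

test_that("builds are reproducible given the seed", {
  m1 <- build_vpnet("S", input_size = 24, seed = 11)
  m2 <- build_vpnet("S", input_size = 24, seed = 11)
  expect_identical(m1$layers$cbr1_conv$params$W, m2$layers$cbr1_conv$params$W)
  expect_identical(m1$layers$head$params$W, m2$layers$head$params$W)
})

test_that("analytic gradients match finite differences in every layer type", {
  set.seed(42)
  m <- build_vpnet("S", input_size = 16, seed = 7)
  x <- array(runif(16 * 16 * 1 * 3), c(16, 16, 1, 3))
  y <- c(3, 7, 11)
  loss_fn <- function(model) {
    fw <- ns$model_forward(model, x, training = TRUE, keep_cache = TRUE)
    list(loss = mean(abs(fw$y - y)), fw = fw,
         dY = sign(fw$y - y) / length(y))
  }
  r <- loss_fn(m)
  bw <- ns$model_backward(m, r$dY, r$fw$caches)
  eps <- 1e-5
  checked <- character()
  for (i in seq_along(m$layers)) {
    ly <- m$layers[[i]]
    if (length(ly$params) == 0 || ly$type %in% checked) next
    checked <- c(checked, ly$type)
    for (nm in names(ly$params)) {
      p <- ly$params[[nm]]
      for (j in sample(length(p), min(3, length(p)))) {
        m2 <- m
        m2$layers[[i]]$params[[nm]][j] <- p[j] + eps
        lp <- loss_fn(m2)$loss
        m2$layers[[i]]$params[[nm]][j] <- p[j] - eps
        lm_ <- loss_fn(m2)$loss
        num <- (lp - lm_) / (2 * eps)
        ana <- bw$grads[[i]][[nm]][j]
        if (abs(num) < 1e-7 && abs(ana) < 1e-7) next  # null direction
        expect_lt(abs(num - ana) / max(abs(num) + abs(ana), 1e-8), 2e-4,
                  label = sprintf("grad %s/%s[%d]", ly$name, nm, j))
      }
    }
  }
  expect_setequal(checked, c("conv", "bn", "dwconv", "pwconv", "se", "dense"))
})
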