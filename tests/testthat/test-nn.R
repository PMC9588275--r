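# Backpropagation is checked against central finite differences on small
# tensors: this is the ground truth for the whole training engine.

numeric_grad <- function(f, x, i, eps = 1e-5) {
  xp <- x; xp[i] <- xp[i] + eps
  xm <- x; xm[i] <- xm[i] - eps
  (f(xp) - f(xm)) / (2 * eps)
}

test_that("generator forward shape contract and architecture accounting", {
  gen <- tiny_generator()
  x <- array(runif(64), c(8, 8, 1))
  out <- cyclect:::generator_apply(gen, x)$out
  expect_identical(dim(out), dim(x))
  expect_equal(conv_layers_total(generator_spec(9L, 64L, 3L)), 27L)
  expect_equal(conv_layers_total(generator_spec(1L, 8L, 1L)), 7L)
  expect_error(cyclect:::generator_apply(gen, array(0, c(9, 9, 1))),
               "divisible")
})

test_that("discriminator emits patch scores in (0, 1)", {
  disc <- tiny_discriminator()
  x <- array(runif(256), c(16, 16, 1))
  out <- cyclect:::net_forward(disc$layers, x, keep_cache = FALSE)$out
  expect_gt(length(out), 1)        # per-patch, not a single scalar
  expect_true(all(out > 0 & out < 1))
  expect_gt(discriminator_spec(3L)$receptive_field, 60)
})

test_that("backprop matches finite differences through every layer type", {
  gen <- tiny_generator()
  x <- array(runif(64), c(8, 8, 1))
  f <- cyclect:::generator_apply(gen, x, keep_cache = TRUE)
  b <- cyclect:::net_backward(gen$layers, f$cache, f$out)  # d(sum(out^2)/2)
  loss <- function(layers) {
    sum(cyclect:::net_forward(layers, x, keep_cache = FALSE)$out^2) / 2
  }
  # global-skip generator: all layers sit inside the outer residual block
  inner <- gen$layers[[1]]$layers
  ig <- b$grads[[1]]
  conv_idx <- which(vapply(inner, function(l) l$type == "conv", logical(1)))
  inorm_idx <- which(vapply(inner, function(l) l$type == "inorm", logical(1)))
  for (ly in conv_idx) {
    ana <- ig[[ly]]$dw[2]
    f2 <- function(w2) {
      g2 <- gen$layers
      g2[[1]]$layers[[ly]]$w[2] <- w2
      loss(g2)
    }
    num <- numeric_grad(f2, gen$layers[[1]]$layers[[ly]]$w[2], 1)
    expect_equal(ana, num, tolerance = 1e-5)
  }
  ly <- inorm_idx[1]
  f3 <- function(g0) {
    g2 <- gen$layers
    g2[[1]]$layers[[ly]]$gamma[1] <- g0
    loss(g2)
  }
  expect_equal(ig[[ly]]$dgamma[1],
               numeric_grad(f3, gen$layers[[1]]$layers[[ly]]$gamma[1], 1),
               tolerance = 1e-5)
  # input gradient
  i <- 13L
  fx0 <- function(xx) {
    sum(cyclect:::net_forward(gen$layers, xx, keep_cache = FALSE)$out^2) / 2
  }
  expect_equal(b$dx[i], numeric_grad(fx0, x, i), tolerance = 1e-5)
})

test_that("discriminator backprop matches finite differences", {
  disc <- tiny_discriminator()
  x <- array(runif(256), c(16, 16, 1))
  fd <- cyclect:::net_forward(disc$layers, x, keep_cache = TRUE)
  bd <- cyclect:::net_backward(disc$layers, fd$cache, array(1, dim(fd$out)))
  loss <- function(layers) {
    sum(cyclect:::net_forward(layers, x, keep_cache = FALSE)$out)
  }
  for (ly in seq_along(disc$layers)) {
    g <- bd$grads[[ly]]
    if (is.null(g) || is.null(g$dw)) next
    f2 <- function(w1) {
      d2 <- disc$layers
      d2[[ly]]$w[1] <- w1
      loss(d2)
    }
    expect_equal(g$dw[1], numeric_grad(f2, disc$layers[[ly]]$w[1], 1),
                 tolerance = 1e-5)
  }
})

test_that("perceptual gradient matches finite differences", {
  fx <- feature_extractor(seed = 5, channels1 = 4L, channels2 = 4L)
  set.seed(12)
  x <- array(runif(64), c(8, 8, 1))
  orig <- array(runif(64), c(8, 8, 1))
  pg <- cyclect:::perceptual_loss_grad(x, orig, fx)
  for (i in c(3L, 40L)) {
    num <- numeric_grad(function(xx) perceptual_cycle_loss(xx, orig, fx), x, i)
    expect_equal(pg$grad[i], num, tolerance = 1e-4)
  }
  expect_equal(pg$loss, perceptual_cycle_loss(x, orig, fx), tolerance = 1e-12)
})

test_that("Adam updates move parameters and are deterministic", {
  gen1 <- tiny_generator(seed = 21)
  gen2 <- tiny_generator(seed = 21)
  x <- array(runif(64), c(8, 8, 1))
  step_once <- function(gen) {
    f <- cyclect:::generator_apply(gen, x, keep_cache = TRUE)
    b <- cyclect:::net_backward(gen$layers, f$cache, f$out)
    r <- cyclect:::adam_step(gen$layers, b$grads, cyclect:::adam_init(), 1e-3)
    r$layers
  }
  l1 <- step_once(gen1)
  l2 <- step_once(gen2)
  expect_identical(l1, l2)
  expect_false(identical(l1, gen1$layers))
})
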