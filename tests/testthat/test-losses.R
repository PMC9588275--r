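test_that("HU normalisation maps the anchor values and round-trips", {
  spec <- normalization_spec()
  expect_equal(normalize_hu(-1000, spec), 0)
  expect_equal(normalize_hu(1000, spec), 1)
  expect_equal(normalize_hu(0, spec), 0.5)
  expect_equal(normalize_hu(-2000, spec), 0)
  expect_equal(normalize_hu(2500, spec), 1)
  x <- seq(-2000, 3000, by = 7)
  expect_equal(denormalize_hu(normalize_hu(x, spec), spec),
               pmin(pmax(x, -1000), 1000), tolerance = 1e-12)
  expect_error(normalization_spec(10, -10), "below")
})

test_that("adversarial loss matches closed forms and the elementwise oracle", {
  eps <- 1e-9
  expect_equal(adversarial_loss(1 - eps, eps), 0, tolerance = 1e-6)
  expect_equal(adversarial_loss(0.5, 0.5), 2 * log(0.5), tolerance = 1e-12)
  expect_equal(adversarial_loss(0.5, 0.5), -1.3863, tolerance = 1e-4)
  set.seed(8)
  dr <- runif(16, 0.01, 0.99)
  df <- runif(16, 0.01, 0.99)
  oracle <- mean(log(dr)) + mean(log(1 - df))
  expect_equal(adversarial_loss(dr, df), oracle, tolerance = 1e-12)
  expect_error(adversarial_loss(c(0.5, 1.2), 0.5), "0, 1")
  expect_error(adversarial_loss(0.5, 0), "0, 1")
})

test_that("total objective combines terms with the lambda weight", {
  expect_equal(total_objective(-1.0, 0.2, 10), 1.0, tolerance = 1e-12)
  expect_equal(total_objective(-0.7, 0, 10), -0.7)
  expect_equal(total_objective(-0.7, 0.5, 0), -0.7)
  expect_equal(training_config()$lambda_cyc, 10)
  expect_error(total_objective(-1, 0.1, -2), "non-negative")
  expect_error(total_objective(Inf, 0.1, 1), "finite")
})

test_that("perceptual loss is zero for identical inputs and symmetric", {
  fx <- feature_extractor(seed = 5, channels1 = 4L, channels2 = 4L)
  set.seed(9)
  a <- matrix(runif(64), 8, 8)
  b <- matrix(runif(64), 8, 8)
  expect_equal(perceptual_cycle_loss(a, a, fx), 0)
  expect_equal(perceptual_cycle_loss(a, b, fx),
               perceptual_cycle_loss(b, a, fx), tolerance = 1e-12)
  expect_gt(perceptual_cycle_loss(a, b, fx), 0)
  expect_error(perceptual_cycle_loss(a, matrix(0, 4, 4), fx), "shapes")
})

test_that("perceptual loss equals a hand-computed single-filter oracle", {
  # one 3x3 filter, no pooling: features are a plain convolution
  w <- array(0, c(3, 3, 3, 1))
  w[, , 1, 1] <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  lay <- list(list(type = "conv", w = w, b = 0, stride = 1L, pad = 1L))
  fx <- cyclect:::feature_extractor_from_layers(lay)
  set.seed(10)
  a <- matrix(runif(16), 4, 4)
  b <- matrix(runif(16), 4, 4)
  manual_conv <- function(img) {
    p <- matrix(0, 6, 6)
    p[2:5, 2:5] <- img
    out <- matrix(0, 4, 4)
    k <- w[, , 1, 1]
    for (i in 1:4) for (j in 1:4) {
      out[i, j] <- sum(p[i:(i + 2), j:(j + 2)] * k)
    }
    out
  }
  oracle <- sum((manual_conv(a) - manual_conv(b))^2) / 16
  expect_equal(perceptual_cycle_loss(a, b, fx), oracle, tolerance = 1e-10)
})

test_that("the feature extractor is deterministic and offline-capable", {
  fx1 <- feature_extractor(seed = 17)
  fx2 <- feature_extractor(seed = 17)
  x <- matrix(runif(64), 8, 8)
  expect_identical(feature_maps(fx1, x), feature_maps(fx2, x))
  d <- dim(feature_maps(fx1, x))
  expect_equal(d[1:2], c(4L, 4L))   # conv2_1-like half resolution
  expect_error(feature_extractor(backend = "pretrained_vgg16"),
               "weights_file")
})
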