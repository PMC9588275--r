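#' Perceptual feature extractor
#'
#' Fixed convolutional feature extractor used by the perceptual
#' cycle-consistency loss. Single-channel images in \[0, 1\] are triplicated
#' to RGB, rescaled to the backend's canonical input range, and passed
#' through the backend network; the loss then compares feature maps rather
#' than pixels.
#'
#' Two backends are defined. `"seeded_random_conv"` is a fixed, seeded
#' two-stage random convolutional network (conv-ReLU-average pool-
#' conv-ReLU) whose feature map lives at half resolution, mirroring the
#' resolution and role of a VGG-16 `conv2_1` map; random projections
#' preserve relative distances well enough for a feature-space distance,
#' and the backend works fully offline and deterministically.
#' `"pretrained_vgg16"` requires a VGG-16 weights file converted to R
#' arrays; if `weights_file` is missing an informative error is raised.
#'
#' @param backend `"seeded_random_conv"` or `"pretrained_vgg16"`.
#' @param seed RNG seed for the random backend (fixed weights).
#' @param channels1,channels2 widths of the two random conv stages.
#' @param output_scale multiplier applied to the random backend's feature
#'   map. VGG feature activations are large, and perceptual distances
#'   reported for CT denoising sit around 0.02-0.08 for noisy/denoised
#'   image pairs; unit-variance random-conv features would yield distances
#'   two orders of magnitude smaller, which silently rescales any
#'   trade-off weight balanced against an adversarial term. The default
#'   puts this backend's distances on the conventional scale.
#' @param layer_tag label of the feature map the loss reads (for
#'   provenance; the random backend always exposes its final map).
#' @param weights_file path to converted VGG-16 weights (RDS), only for the
#'   pretrained backend.
#'
#' @return An object of class `feature_extractor` with elements `backend`,
#'   `layer_tag`, `layers` and `input_scale`.
#' @export
feature_extractor <- function(backend = c("seeded_random_conv", "pretrained_vgg16"),
                              seed = 17L, channels1 = 16L, channels2 = 32L,
                              output_scale = 10,
                              layer_tag = "conv2_1", weights_file = NULL) {
  backend <- match.arg(backend)
  if (backend == "pretrained_vgg16") {
    if (is.null(weights_file) || !file.exists(weights_file)) {
      stopf(paste("backend 'pretrained_vgg16' needs `weights_file`, an RDS of",
                  "VGG-16 conv weights as [kh, kw, Cin, Cout] arrays; no such",
                  "file was given. Use backend = 'seeded_random_conv' for a",
                  "self-contained extractor."))
    }
    wts <- readRDS(weights_file)
    layers <- wts$layers
    scale <- wts$input_scale
    scale_deriv <- wts$input_scale_deriv
  } else {
    layers <- with_seed(seed, list(
      init_conv_layer(3L, 3L, 3L, channels1),
      layer_relu(),
      layer_avgpool(2L),
      init_conv_layer(3L, 3L, channels1, channels2),
      layer_relu()
    ))
    layers[[4]]$w <- layers[[4]]$w * output_scale
    scale <- function(x) 2 * x - 1
    scale_deriv <- 2
  }
  structure(list(backend = backend, layer_tag = layer_tag, seed = seed,
                 layers = layers, input_scale = scale,
                 input_scale_deriv = scale_deriv),
            class = "feature_extractor")
}

# internal: build an extractor from explicit layers (unit-test oracle use)
feature_extractor_from_layers <- function(layers, input_scale = identity,
                                          input_scale_deriv = 1) {
  structure(list(backend = "custom", layer_tag = "custom", layers = layers,
                 input_scale = input_scale,
                 input_scale_deriv = input_scale_deriv),
            class = "feature_extractor")
}

# triplicate one channel to RGB and apply canonical scaling
fx_prepare <- function(x, fx) {
  x <- as.array(x)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x3 <- array(rep(x, 3L), dim = c(dim(x), 3L))
  fx$input_scale(x3)
}

#' Extract perceptual feature maps
#'
#' @param fx a [feature_extractor()].
#' @param image 2-D matrix (or `[H, W, 1]` array) in \[0, 1\].
#' @return A `[w, e, d]` feature array.
#' @export
feature_maps <- function(fx, image) {
  net_forward(fx$layers, fx_prepare(image, fx), keep_cache = FALSE)$out
}

#' Perceptual cycle-consistency loss
#'
#' Mean squared distance between the feature maps of a reconstructed image
#' and the original it should reproduce:
#' `(1 / (w * e * d)) * || F(reconstructed) - F(original) ||^2`, where `F`
#' is the configured feature extractor applied after RGB triplication, and
#' `w`, `e`, `d` are the feature-map width, height and depth. Replacing the
#' pixelwise MSE of the original cycle-consistency term with this feature
#' distance makes the cycle penalty insensitive to the exact noise
#' realisation a reverse generator cannot reproduce.
#'
#' @param reconstructed,original images of identical shape in \[0, 1\].
#' @param fx a [feature_extractor()].
#' @return Scalar loss value (symmetric in its two image arguments).
#' @export
perceptual_cycle_loss <- function(reconstructed, original, fx) {
  if (!identical(dim(as.array(reconstructed)), dim(as.array(original)))) {
    stopf("image shapes differ: %s vs %s",
          paste(dim(as.array(reconstructed)), collapse = "x"),
          paste(dim(as.array(original)), collapse = "x"))
  }
  f1 <- feature_maps(fx, reconstructed)
  f2 <- feature_maps(fx, original)
  sum((f1 - f2)^2) / prod(dim(f1))
}

#' @rdname perceptual_cycle_loss
#' @export
perceptual_distance <- perceptual_cycle_loss

# internal: loss value plus gradient w.r.t. `reconstructed`
perceptual_loss_grad <- function(reconstructed, original, fx) {
  x1 <- fx_prepare(reconstructed, fx)
  r1 <- net_forward(fx$layers, x1, keep_cache = TRUE)
  f2 <- feature_maps(fx, original)
  diff <- r1$out - f2
  wed <- prod(dim(diff))
  loss <- sum(diff^2) / wed
  b <- net_backward(fx$layers, r1$cache, 2 * diff / wed, want_grads = FALSE)
  # chain through triplication (sum over RGB) and the canonical input scaling
  dimg <- (b$dx[, , 1] + b$dx[, , 2] + b$dx[, , 3]) * fx$input_scale_deriv
  dim(dimg) <- c(dim(dimg), 1L)
  list(loss = loss, grad = dimg)
}
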