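#' Generator architecture specification
#'
#' Residual image-to-image translator: an initial 7x7 convolution,
#' `n_down` stride-2 downsampling convolutions (channel width doubling),
#' `n_res_blocks` residual blocks of two 3x3 convolutions, `n_down`
#' nearest-neighbour-upsample + 3x3 convolution stages, a 3x3 refinement
#' convolution and a 1x1 linear output convolution. Instance normalisation
#' follows every convolution except the output (batch size is 1, which
#' makes batch statistics degenerate). The derived convolution-layer count
#' is `2 * n_res_blocks + 2 * n_down + 3`; the full-scale configuration
#' (9 residual blocks, 3 resolution stages) therefore has 27 convolutional
#' layers. Output spatial size always equals input size.
#'
#' @param n_res_blocks number of residual blocks (full scale: 9).
#' @param base_channels channels after the initial convolution.
#' @param n_down number of downsampling (and matching upsampling) stages.
#' @param global_skip add a global input-to-output residual connection, so
#'   the network predicts a correction to its input rather than the image
#'   from scratch. Denoising is a near-identity mapping, and the skip makes
#'   the untrained generator start close to it, which anchors the cycle
#'   loss from the first step.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(n_res_blocks = 9L, base_channels = 64L,
                           n_down = 3L, global_skip = TRUE) {
  stopifnot(n_res_blocks >= 0, base_channels >= 1, n_down >= 0)
  structure(list(n_res_blocks = as.integer(n_res_blocks),
                 base_channels = as.integer(base_channels),
                 n_down = as.integer(n_down),
                 global_skip = isTRUE(global_skip)),
            class = "generator_spec")
}

#' @rdname generator_spec
#' @param spec a `generator_spec`.
#' @export
conv_layers_total <- function(spec) {
  2L * spec$n_res_blocks + 2L * spec$n_down + 3L
}

#' Patch discriminator specification
#'
#' PatchGAN-style discriminator: `n_layers` stride-2 4x4 convolutions with
#' leaky ReLU (instance normalisation from the second layer on), one
#' stride-1 4x4 convolution, and a final 4x4 convolution to a 1-channel
#' patch map passed through a sigmoid, so every output element is a
#' real/fake score in (0, 1) for one receptive-field patch.
#'
#' @param n_layers number of stride-2 layers (3 gives the usual 70x70
#'   receptive field at full scale).
#' @param base_channels channels after the first convolution.
#' @return An object of class `discriminator_spec`.
#' @export
discriminator_spec <- function(n_layers = 3L, base_channels = 64L) {
  stopifnot(n_layers >= 1, base_channels >= 1)
  rf <- 4L + 3L                                           # two stride-1 4x4
  for (i in seq_len(n_layers)) rf <- (rf - 1L) * 2L + 4L  # stride-2 stack
  structure(list(n_layers = as.integer(n_layers),
                 base_channels = as.integer(base_channels),
                 receptive_field = rf),
            class = "discriminator_spec")
}

build_generator <- function(spec) {
  c0 <- spec$base_channels
  layers <- list(
    init_conv_layer(7L, 7L, 1L, c0),
    layer_inorm(c0),
    layer_relu()
  )
  ch <- c0
  for (i in seq_len(spec$n_down)) {
    layers <- c(layers, list(
      init_conv_layer(3L, 3L, ch, ch * 2L, stride = 2L),
      layer_inorm(ch * 2L),
      layer_relu()
    ))
    ch <- ch * 2L
  }
  for (i in seq_len(spec$n_res_blocks)) {
    layers <- c(layers, list(layer_residual(list(
      init_conv_layer(3L, 3L, ch, ch),
      layer_inorm(ch),
      layer_relu(),
      init_conv_layer(3L, 3L, ch, ch),
      layer_inorm(ch)
    ))))
  }
  for (i in seq_len(spec$n_down)) {
    layers <- c(layers, list(
      layer_upsample(2L),
      init_conv_layer(3L, 3L, ch, ch %/% 2L),
      layer_inorm(ch %/% 2L),
      layer_relu()
    ))
    ch <- ch %/% 2L
  }
  layers <- c(layers, list(
    init_conv_layer(3L, 3L, ch, ch),
    layer_inorm(ch),
    layer_relu(),
    init_conv_layer(1L, 1L, ch, 1L,
                    gain = if (spec$global_skip) 1e-6 else 1)
  ))
  if (spec$global_skip) layers <- list(layer_residual(layers))
  list(spec = spec, layers = layers)
}

build_discriminator <- function(spec) {
  c0 <- spec$base_channels
  layers <- list(
    init_conv_layer(4L, 4L, 1L, c0, stride = 2L, pad = 1L),
    layer_lrelu(0.2)
  )
  ch <- c0
  for (i in seq_len(spec$n_layers - 1L)) {
    layers <- c(layers, list(
      init_conv_layer(4L, 4L, ch, ch * 2L, stride = 2L, pad = 1L),
      layer_inorm(ch * 2L),
      layer_lrelu(0.2)
    ))
    ch <- ch * 2L
  }
  layers <- c(layers, list(
    init_conv_layer(4L, 4L, ch, ch, stride = 1L, pad = 1L),
    layer_inorm(ch),
    layer_lrelu(0.2),
    init_conv_layer(4L, 4L, ch, 1L, stride = 1L, pad = 1L),
    layer_sigmoid()
  ))
  list(spec = spec, layers = layers)
}

generator_apply <- function(gen, x, keep_cache = FALSE) {
  d <- dim(x)
  f <- 2L^gen$spec$n_down
  if (d[1] %% f != 0 || d[2] %% f != 0) {
    stopf("generator with %d downsampling stages needs spatial dims divisible by %d (got %d x %d)",
          gen$spec$n_down, f, d[1], d[2])
  }
  net_forward(gen$layers, x, keep_cache = keep_cache)
}
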