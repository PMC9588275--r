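#' HU normalisation for network training
#'
#' CT values are clipped to \[-1000, 1000\] HU and mapped affinely to
#' \[0, 1\] before entering the networks; [denormalize_hu()] inverts the
#' affine map exactly, so `denormalize_hu(normalize_hu(x))` equals
#' `clip(x, -1000, 1000)`.
#'
#' @param hu_floor,hu_ceiling clipping bounds in HU.
#' @return `normalization_spec()` returns an object of class
#'   `normalization_spec`.
#' @export
normalization_spec <- function(hu_floor = -1000, hu_ceiling = 1000) {
  if (!(hu_floor < hu_ceiling)) stopf("`hu_floor` must be below `hu_ceiling`")
  structure(list(hu_floor = hu_floor, hu_ceiling = hu_ceiling,
                 out_range = c(0, 1)),
            class = "normalization_spec")
}

#' @rdname normalization_spec
#' @param x numeric array/matrix/vector of HU values (or a [ct_volume()]).
#' @param spec a [normalization_spec()].
#' @export
normalize_hu <- function(x, spec = normalization_spec()) {
  if (inherits(x, "ct_volume")) {
    x$voxels <- normalize_hu(x$voxels, spec)
    return(x)
  }
  (clamp(x, spec$hu_floor, spec$hu_ceiling) - spec$hu_floor) /
    (spec$hu_ceiling - spec$hu_floor)
}

#' @rdname normalization_spec
#' @export
denormalize_hu <- function(x, spec = normalization_spec()) {
  if (inherits(x, "ct_volume")) {
    x$voxels <- denormalize_hu(x$voxels, spec)
    return(x)
  }
  x * (spec$hu_ceiling - spec$hu_floor) + spec$hu_floor
}

#' Adversarial loss of one GAN direction
#'
#' The value `E[log D(real)] + E[log(1 - D(fake))]` over batches of
#' discriminator scores: the discriminator maximises it, the generator
#' minimises it. Scores must already be in (0, 1) (i.e. after the sigmoid);
#' pre-activation inputs are rejected.
#'
#' @param d_real,d_fake numeric vectors/arrays of discriminator scores in
#'   (0, 1).
#' @return Scalar loss value (non-positive; 0 only for a perfect
#'   discriminator).
#' @export
adversarial_loss <- function(d_real, d_fake) {
  d_real <- as.numeric(d_real)
  d_fake <- as.numeric(d_fake)
  if (any(d_real <= 0 | d_real >= 1) || any(d_fake <= 0 | d_fake >= 1)) {
    stopf("discriminator scores must lie strictly inside (0, 1); pass pre-sigmoid outputs through the activation first")
  }
  mean(log(d_real)) + mean(log(1 - d_fake))
}

#' Combined cycle GAN objective
#'
#' `L_adv + lambda * L_cyc`: the adversarial terms of both directions plus
#' the perceptual cycle-consistency terms weighted by the trade-off
#' parameter `lambda` (default 10). With `lambda = 0` it reduces to the
#' pure adversarial objective.
#'
#' @param adv total adversarial loss (both directions).
#' @param cyc total perceptual cycle-consistency loss (both directions).
#' @param lambda_cyc non-negative trade-off weight.
#' @return Scalar objective value.
#' @export
total_objective <- function(adv, cyc, lambda_cyc = 10) {
  if (!is_scalar_number(lambda_cyc) || lambda_cyc < 0) {
    stopf("`lambda_cyc` must be a non-negative number")
  }
  if (!is.finite(adv) || !is.finite(cyc)) stopf("loss terms must be finite")
  adv + lambda_cyc * cyc
}
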