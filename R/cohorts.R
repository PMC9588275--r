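#' Build unpaired low-dose and high-dose phantom cohorts
#'
#' Generates two disjoint cohorts of synthetic subjects: the low-dose
#' cohort is built from `spec_a` phantoms pushed through the sinogram
#' dose simulation, the high-dose cohort consists of clean `spec_b`
#' phantoms from different subjects. The two phantom specifications may
#' differ only in seed and `body_scale`; a body-size difference injects the
#' kind of cohort-level domain shift seen between clinical populations
#' (one cohort systematically thinner than the other). Per-subject seeds
#' are derived deterministically from each spec's seed, so identical spec
#' seeds would produce overlapping subjects and are rejected.
#'
#' @param spec_a phantom spec for the low-dose cohort.
#' @param spec_b phantom spec for the high-dose cohort (seed and
#'   `body_scale` may differ from `spec_a`; all other fields must match).
#' @param config_a dose configuration applied to cohort A.
#' @param n_low,n_high cohort sizes.
#'
#' @details High-dose scans are images too: every cohort member passes
#' through the same forward-projection / filtered-back-projection chain,
#' the high-dose cohort without quantum noise and the low-dose cohort with
#' it. The noise-free reconstruction of each low-dose subject is returned
#' as its "original high-dose CT" (`clean_low`), the reference against
#' which denoising is evaluated — mirroring the setting where low-dose
#' scans are simulated from acquired high-dose scans by adding noise to
#' their sinograms. Comparing against the ideal phantom instead would
#' conflate quantum noise with the scanner's resolution limit and reward
#' (or provoke) sharpening beyond the data.
#'
#' @return A list with `low` (simulated low-dose volumes), `high`
#'   (noise-free high-dose volumes), `clean_low` (noise-free counterparts
#'   of `low`) and `masks_low` (lesion masks of the low cohort).
#' @export
make_unpaired_cohorts <- function(spec_a, spec_b, config_a,
                                  n_low = 10L, n_high = 10L) {
  stopifnot(inherits(spec_a, "phantom_spec"), inherits(spec_b, "phantom_spec"))
  if (spec_a$seed == spec_b$seed) {
    stopf("`spec_a` and `spec_b` must use different seeds: cohort subjects must be disjoint")
  }
  fixed <- function(s) s[!(names(s) %in% c("seed", "body_scale"))]
  if (!identical(fixed(unclass(spec_a)), fixed(unclass(spec_b)))) {
    stopf("`spec_a` and `spec_b` may differ only in `seed` and `body_scale`")
  }
  gen_subject <- function(spec, i, prefix) {
    s <- spec
    s$seed <- derive_seed(spec$seed, i, 1L)
    vol <- generate_phantom(s)
    vol$subject_id <- sprintf("%s%02d", prefix, i)
    vol
  }
  phantoms_low <- lapply(seq_len(n_low),
                         function(i) gen_subject(spec_a, i, "low"))
  low <- lapply(seq_len(n_low), function(i) {
    cfg <- config_a
    cfg$noise_seed <- derive_seed(config_a$noise_seed, i, 2L)
    simulate_low_dose(phantoms_low[[i]], cfg)
  })
  clean_low <- lapply(phantoms_low, fbp_reference, config = config_a)
  high <- lapply(seq_len(n_high), function(i) {
    fbp_reference(gen_subject(spec_b, i, "high"), config_a)
  })
  list(low = low, high = high, clean_low = clean_low,
       masks_low = lapply(phantoms_low, attr, "lesion_mask"))
}

# noise-free acquisition: forward projection + FBP of every slice (the
# "original high-dose CT" of a phantom)
fbp_reference <- function(volume, config) {
  d <- dim(volume$voxels)
  out <- array(0, d)
  for (iz in seq_len(d[3])) {
    sino <- forward_project(volume$voxels[, , iz], config,
                            pixel_mm = volume$spacing[1])
    out[, , iz] <- reconstruct(sino, image_size = d[1], config = config)
  }
  res <- ct_volume(out, spacing = volume$spacing,
                   subject_id = volume$subject_id)
  for (a in c("lesion_mask", "lung_mask", "body_mask", "lesions")) {
    attr(res, a) <- attr(volume, a)
  }
  res
}
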