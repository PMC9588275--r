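cfg64 <- dose_sim_config(n_angles = 90L)

test_that("all-air slices project to an all-zero sinogram", {
  img <- matrix(-1000, 48, 48)
  s <- forward_project(img, dose_sim_config(n_angles = 60L))
  expect_true(all(s$values == 0))
})

test_that("projection conserves attenuation mass across angles", {
  img <- disk_image(64)
  s <- forward_project(img, cfg64, pixel_mm = 1)
  masses <- rowSums(s$values) * s$bin_width
  expect_lt(max(abs(masses / mean(masses) - 1)), 0.01)
  # mass equals the disk's total attenuation within discretisation error
  mu <- dose_sim_config()$hu_to_mu_scale * 1000   # water per mm
  expect_equal(mean(masses), sum(img > -1000) * mu, tolerance = 0.02)
})

test_that("shifting the object preserves mass and shifts the sinusoid", {
  n <- 64
  img <- disk_image(n, radius = 8)
  img_shift <- matrix(-1000, n, n)
  img_shift[, 1:(n - 6)] <- img[, 7:n]   # shift 6 pixels
  s0 <- forward_project(img, cfg64)
  s1 <- forward_project(img_shift, cfg64)
  expect_equal(sum(s0$values), sum(s1$values), tolerance = 0.01)
  # at angle 90 deg the profile moves by the shift along the detector
  i90 <- which.min(abs(s0$angles - 90))
  c0 <- which.max(s0$values[i90, ])
  c1 <- which.max(s1$values[i90, ])
  expect_equal(abs(c0 - c1), 6, tolerance = 1)
})

test_that("non-square input and inadequate angular sampling error", {
  expect_error(forward_project(matrix(0, 4, 6), cfg64), "square")
  expect_error(forward_project(matrix(0, 128, 128), cfg64), "n_angles")
})

test_that("quantum noise is seeded, seed-sensitive and Poisson-unbiased", {
  img <- disk_image(32, radius = 10)
  s <- forward_project(img, dose_sim_config(n_angles = 45L))
  c1 <- dose_sim_config(n_angles = 45L, noise_seed = 1L,
                        incident_intensity = 1e4)
  c2 <- dose_sim_config(n_angles = 45L, noise_seed = 2L,
                        incident_intensity = 1e4)
  n1a <- inject_quantum_noise(s, c1)
  n1b <- inject_quantum_noise(s, c1)
  n2 <- inject_quantum_noise(s, c2)
  expect_identical(n1a$values, n1b$values)
  expect_false(identical(n1a$values, n2$values))
})

test_that("transmission-domain noise has Poisson variance equal to its mean", {
  p <- 1.3              # one line integral
  i0 <- 2000
  s <- sinogram(matrix(p, 1, 1), 0)
  draws <- vapply(seq_len(10000), function(k) {
    cfg <- dose_sim_config(n_angles = 1L, incident_intensity = i0,
                           noise_seed = k)
    i0 * exp(-inject_quantum_noise(s, cfg)$values[1, 1])
  }, numeric(1))
  lambda <- i0 * exp(-p)
  expect_equal(mean(draws), lambda, tolerance = 0.02)
  expect_equal(var(draws), lambda, tolerance = 0.05)
})

test_that("the vanishing-noise limit returns the clean sinogram", {
  img <- disk_image(32, radius = 10)
  s <- forward_project(img, dose_sim_config(n_angles = 45L))
  cfg <- dose_sim_config(n_angles = 45L, incident_intensity = 1e12)
  n <- inject_quantum_noise(s, cfg)
  expect_lt(max(abs(n$values - s$values)), 1e-3)
})

test_that("FBP round-trips a noise-free phantom", {
  img <- disk_image(64)
  s <- forward_project(img, cfg64)
  rec <- reconstruct(s, 64, cfg64)
  nrm <- function(x) normalize_hu(x)
  r <- attr(img, "r")
  interior <- r <= 12 | (r >= 20 & r <= 28)   # away from the edge discontinuity
  expect_lt(sqrt(mean((nrm(rec)[interior] - nrm(img)[interior])^2)), 0.02)
  # smooth phantom: global round-trip accuracy
  blob <- matrix(-1000 + 800 * exp(-r^2 / 100), 64, 64)
  rec2 <- reconstruct(forward_project(blob, cfg64), 64, cfg64)
  expect_lt(sqrt(mean((nrm(rec2) - nrm(blob))^2)), 0.02)
})

test_that("FBP maps a zero sinogram to air and is linear", {
  z <- sinogram(matrix(0, 90, 64), seq(0, 178, length.out = 90))
  expect_true(all(reconstruct(z, 64, cfg64) == -1000))
  img <- disk_image(64, radius = 10, inside_hu = -500)
  s <- forward_project(img, cfg64)
  s2 <- s; s2$values <- 2 * s$values
  mu <- function(h) cfg64$hu_to_mu_scale * (h + 1000)
  r1 <- mu(reconstruct(s, 64, cfg64))
  r2 <- mu(reconstruct(s2, 64, cfg64))
  expect_equal(r2, 2 * r1, tolerance = 0.05)
})

test_that("insufficient angular coverage is rejected", {
  img <- disk_image(32, radius = 8)
  s <- forward_project(img, dose_sim_config(n_angles = 45L))
  half <- sinogram(s$values[1:20, ], s$angles[1:20], s$bin_width)
  expect_error(reconstruct(half, 32), "coverage")
})

test_that("dose presets order as low_noise > high_noise intensity", {
  lo <- dose_preset("low_noise")
  hi <- dose_preset("high_noise")
  expect_gt(lo$incident_intensity, hi$incident_intensity)
})

test_that("SNR decreases monotonically down a three-level dose ladder", {
  spec <- tiny_phantom_spec(seed = 5L)
  clean <- generate_phantom(spec)
  snrs <- vapply(c(1e6, 1e5, 1e4), function(i0) {
    cfg <- dose_sim_config(n_angles = 45L, incident_intensity = i0,
                           noise_seed = 42L)
    # reference is the noise-free acquisition, so only quantum noise varies
    ref <- cyclect:::fbp_reference(clean, cfg)
    noisy <- simulate_low_dose(clean, cfg)
    mean(vapply(seq_len(dim(clean)[3]), function(iz) {
      as.numeric(snr_db(normalize_hu(ref$voxels[, , iz]),
                        normalize_hu(noisy$voxels[, , iz])))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(snrs) < 0))
})

test_that("low-dose simulation is deterministic and preserves metadata", {
  clean <- generate_phantom(tiny_phantom_spec(seed = 6L))
  cfg <- dose_preset("high_noise", n_angles = 45L, noise_seed = 3L)
  a <- simulate_low_dose(clean, cfg)
  b <- simulate_low_dose(clean, cfg)
  expect_identical(a$voxels, b$voxels)
  expect_identical(a$spacing, clean$spacing)
  expect_identical(a$subject_id, clean$subject_id)
})

test_that("infinite-dose simulation approaches the FBP round-trip", {
  clean <- generate_phantom(tiny_phantom_spec(seed = 8L, lesion_count = 0L))
  cfg_inf <- dose_sim_config(n_angles = 45L, incident_intensity = 1e12)
  sim <- simulate_low_dose(clean, cfg_inf)
  iz <- 2L
  direct <- reconstruct(forward_project(clean$voxels[, , iz], cfg_inf,
                                        pixel_mm = clean$spacing[1]),
                        32, cfg_inf)
  # residual Poisson jitter at 1e12 photons is a small fraction of an HU
  expect_lt(max(abs(sim$voxels[, , iz] - direct)), 1)
})
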