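test_that("the default manifest reproduces the standard feature accounting", {
  man <- feature_manifest()
  expect_equal(nrow(man), 103L)
  counts <- attr(man, "class_counts")
  expect_equal(unname(counts["shape"]), 13L)
  expect_equal(unname(counts["firstorder"]), 17L)
  expect_equal(sum(counts[cyclect:::texture_classes]), 73L)
  expect_equal(nrow(feature_manifest(exclude_shape = TRUE)), 90L)
  expect_false(anyDuplicated(man$feature) > 0)
  expect_error(feature_manifest(classes = "wavelet"), "unknown")
})

test_that("discretisation follows the fixed-bin-width formula", {
  expect_identical(discretize(c(0, 24.9, 25), bin_width = 25), c(1L, 1L, 2L))
  expect_identical(discretize(rep(7, 5), bin_width = 10), rep(1L, 5L))
  x <- runif(200, -100, 300)
  lv <- discretize(x, 25)
  expect_equal(max(lv), floor((max(x) - min(x)) / 25) + 1)
  expect_error(discretize(numeric(0)), "no intensities")
  expect_error(discretize(1:3, bin_width = 0), "bin_width")
})

test_that("first-order features match their closed forms", {
  cfg <- extraction_config(bin_width = 25)
  # constant region
  fo <- extract_first_order(rep(3, 10), cfg)
  expect_equal(unname(fo["Mean"]), 3)
  expect_equal(unname(fo["Variance"]), 0)
  expect_equal(unname(fo["Energy"]), 10 * 9)
  expect_equal(unname(fo["Entropy"]), 0)
  expect_true(isTRUE(attr(fo, "degenerate")))
  # two voxels {0, 2}: population variance 1
  fo2 <- extract_first_order(c(0, 2), cfg)
  expect_equal(unname(fo2["Mean"]), 1)
  expect_equal(unname(fo2["Variance"]), 1)
  # uniform 4-level histogram has 2 bits of entropy
  x <- c(0, 25, 50, 75) + 0.5
  fo3 <- extract_first_order(x, cfg)
  expect_equal(unname(fo3["Entropy"]), 2)
  expect_equal(unname(fo3["Uniformity"]), 0.25)
  # direct-summation oracle on a random region
  set.seed(5)
  x <- rnorm(50, 100, 40)
  fo4 <- extract_first_order(x, cfg)
  expect_equal(unname(fo4["Energy"]), sum(x^2))
  expect_equal(unname(fo4["RootMeanSquared"]), sqrt(mean(x^2)))
  expect_equal(unname(fo4["Skewness"]),
               mean((x - mean(x))^3) / mean((x - mean(x))^2)^1.5)
  expect_equal(unname(fo4["Kurtosis"]),
               mean((x - mean(x))^4) / mean((x - mean(x))^2)^2)
  expect_equal(unname(fo4["MeanAbsoluteDeviation"]), mean(abs(x - mean(x))))
})

test_that("GLCM counts match the brute-force pair-enumeration oracle", {
  set.seed(6)
  dirs <- cyclect:::glcm_directions()
  expect_equal(nrow(dirs), 13L)
  for (rep_i in 1:3) {
    lv <- array(sample(1:4, 5^3, replace = TRUE), c(5, 5, 5))
    lv[sample(125, 30)] <- NA   # ragged ROI
    ng <- 4L
    for (r in c(1, 5, 13)) {
      fast <- cyclect:::glcm_counts_direction(lv, ng, dirs$dx[r], dirs$dy[r],
                                              dirs$dz[r])
      slow <- brute_glcm_counts(lv, ng, dirs$dx[r], dirs$dy[r], dirs$dz[r])
      expect_equal(unname(as.matrix(fast)), slow)
    }
  }
})

test_that("GLCM features match hand-computed values on a tiny region", {
  # 2x2x1 checkerboard of levels 1/2
  lv <- array(c(1L, 1L, 2L, 2L), c(2, 2, 1))
  cfg <- extraction_config()
  f <- extract_glcm(lv, cfg)
  # constant region: single co-occurrence cell, zero joint entropy
  const <- extract_glcm(array(1L, c(2, 2, 2)), cfg)
  expect_equal(unname(const["JointEntropy"]), 0)
  expect_equal(unname(const["JointEnergy"]), 1)
  expect_equal(unname(const["Contrast"]), 0)
  expect_equal(unname(const["MaximumProbability"]), 1)
  # all features finite on the checkerboard
  expect_true(all(is.finite(f)))
})

test_that("joint entropy is invariant to gray-level relabelling", {
  set.seed(7)
  lv <- array(sample(1:3, 27, replace = TRUE), c(3, 3, 3))
  cfg <- extraction_config()
  f1 <- extract_glcm(lv, cfg)
  perm <- c(3L, 1L, 2L)
  lv2 <- array(perm[lv], dim(lv))
  f2 <- extract_glcm(lv2, cfg)
  expect_equal(f1["JointEntropy"], f2["JointEntropy"], tolerance = 1e-12)
  expect_equal(f1["JointEnergy"], f2["JointEnergy"], tolerance = 1e-12)
  expect_equal(f1["MaximumProbability"], f2["MaximumProbability"],
               tolerance = 1e-12)
})

test_that("isotropic resampling preserves geometry and masked volume", {
  # sphere of radius 20 mm at 1 mm spacing
  n <- 45L
  ctr <- 23
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  r <- sqrt((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2)
  mask <- array(r <= 20, c(n, n, n))
  vol <- ct_volume(array(rnorm(n^3, 0, 30), c(n, n, n)),
                   spacing = c(1, 1, 1))
  rs <- resample_isotropic(vol, mask, spacing = 2)
  expect_equal(dim(rs$volume$voxels), c(23L, 23L, 23L))
  v_in <- sum(mask) * 1
  v_out <- sum(rs$mask) * 8
  expect_equal(v_out, v_in, tolerance = 0.05)
  # input already at target spacing passes through unchanged
  rs2 <- resample_isotropic(ct_volume(vol$voxels, spacing = c(2, 2, 2)),
                            mask, spacing = 2)
  expect_equal(rs2$volume$voxels, vol$voxels, tolerance = 1e-9)
  expect_identical(rs2$mask, mask)
})

test_that("shape features ignore intensity and flag sensible geometry", {
  v <- generate_phantom(phantom_spec(image_size = 48L, n_slices = 6L,
                                     lesion_count = 1L, seed = 9L))
  mask <- attr(v, "lesion_mask")
  cfg <- extraction_config(feature_classes = c("shape", "firstorder", "glcm"),
                           resample_spacing = NULL)
  f1 <- extract_features(v, mask, cfg)
  v2 <- v
  set.seed(1)
  v2$voxels <- v2$voxels + array(rnorm(length(v2$voxels), 0, 50),
                                 dim(v2$voxels))
  v2$voxels <- pmin(pmax(v2$voxels, -1024), 3071)
  f2 <- extract_features(v2, mask, cfg)
  cls <- attr(f1, "feature_class")
  shape_cols <- names(cls)[cls == "shape"]
  other_cols <- names(cls)[cls != "shape"]
  expect_equal(unlist(f1[shape_cols]), unlist(f2[shape_cols]),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(unlist(f1[other_cols]),
                                unlist(f2[other_cols]))))
  expect_gt(f1$shape_Sphericity, 0.3)
  expect_lte(f1$shape_Elongation, 1)
})

test_that("feature extraction is deterministic, complete and order-invariant", {
  vols <- lapply(c(21L, 22L), function(s) {
    generate_phantom(tiny_phantom_spec(seed = s))
  })
  masks <- lapply(vols, attr, "lesion_mask")
  cfg <- extraction_config(feature_classes = c("firstorder", "glcm"))
  t1 <- extract_feature_table(vols, masks, cfg)
  t2 <- extract_feature_table(rev(vols), rev(masks), cfg)
  expect_true(all(!is.na(as.matrix(t1[-1]))))
  expect_setequal(names(t1), c("subject_id", cfg$manifest$feature))
  expect_equal(t1[match(t2$subject_id, t1$subject_id), -1], t2[-1],
               ignore_attr = TRUE)
})

test_that("unsupported manifest entries and bad inputs error informatively", {
  v <- generate_phantom(tiny_phantom_spec())
  mask <- attr(v, "lesion_mask")
  full <- feature_manifest(classes = "glcm")   # includes non-builtin features
  cfg <- extraction_config(feature_classes = "glcm", manifest = full)
  expect_error(extract_features(v, mask, cfg), "does not provide")
  expect_error(extract_features(v, array(FALSE, dim(v$voxels)),
                                extraction_config()), "empty ROI")
  expect_error(extract_features(v, mask[1:10, , ], extraction_config()),
               "shape")
})
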