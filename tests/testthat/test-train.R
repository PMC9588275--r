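# Desk-scale training fixtures: 16x16 phantoms keep the loop fast while
# exercising the full update path.

train_fixture <- function() {
  mk <- function(seed, n) {
    lapply(seq_len(n), function(i) {
      v <- cyclect:::with_seed(seed + i, {
        ct_volume(array(runif(16 * 16 * 3), c(16, 16, 3)),
                  subject_id = sprintf("v%d_%d", seed, i))
      })
    })
  }
  list(low = mk(100, 2), high = mk(200, 2))
}

tiny_bundle <- function(seed = 1L) {
  create_cycle_gan(generator_spec(1L, 4L, 1L),
                   discriminator_spec(1L, 4L),
                   feature_extractor(seed = 5, channels1 = 4L,
                                     channels2 = 4L),
                   seed = seed)
}

test_that("the learning-rate schedule follows the decayed geometric form", {
  cfg <- training_config()
  for (e in c(0, 5, 10, 25, 99, 100)) {
    expect_equal(lr_schedule(e, cfg), 2e-4 * 0.8^(e %/% 10), tolerance = 1e-15)
  }
  expect_equal(lr_schedule(0, cfg), 2e-4)
  expect_error(training_config(n_epochs = 100, checkpoint_every = 30),
               "divide")
})

test_that("training writes the expected checkpoints and records losses", {
  fx <- train_fixture()
  dir <- withr::local_tempdir()
  cfg <- training_config(n_epochs = 2L, checkpoint_every = 1L,
                         steps_per_epoch = 3L, seed = 4L)
  b <- train_cycle_gan(tiny_bundle(), fx$low, fx$high, cfg,
                       checkpoint_dir = dir)
  expect_length(list.files(dir, pattern = "^ckpt_epoch_\\d+\\.rds$"), 2L)
  expect_equal(nrow(b$loss_history), 6L)
  expect_true(all(is.finite(as.matrix(b$loss_history))))
  ck <- load_checkpoint(b$checkpoints[1])
  expect_equal(ck$epoch, 1L)
  expect_s3_class(ck$bundle, "cycle_gan")
})

test_that("training is bit-reproducible under a fixed seed", {
  fx <- train_fixture()
  cfg <- training_config(n_epochs = 1L, checkpoint_every = 1L,
                         steps_per_epoch = 4L, seed = 11L)
  b1 <- train_cycle_gan(tiny_bundle(7L), fx$low, fx$high, cfg)
  b2 <- train_cycle_gan(tiny_bundle(7L), fx$low, fx$high, cfg)
  expect_identical(b1$loss_history, b2$loss_history)
  expect_identical(b1$g_lh$layers, b2$g_lh$layers)
})

test_that("unnormalised cohorts are rejected", {
  fx <- train_fixture()
  bad <- fx$low
  bad[[1]]$voxels <- bad[[1]]$voxels * 1000
  cfg <- training_config(n_epochs = 1L, checkpoint_every = 1L,
                         steps_per_epoch = 1L)
  expect_error(train_cycle_gan(tiny_bundle(), bad, fx$high, cfg),
               "normalised")
})

test_that("denoising preserves shape and metadata, clamps HU and is deterministic", {
  b <- tiny_bundle()
  v <- ct_volume(array(rnorm(16 * 16 * 2, 0, 400), c(16, 16, 2)),
                 spacing = c(2, 2, 4), subject_id = "t")
  d1 <- denoise_volume(b, v)
  d2 <- denoise_volume(b, v)
  expect_identical(d1$voxels, d2$voxels)
  expect_identical(dim(d1$voxels), dim(v$voxels))
  expect_identical(d1$spacing, v$spacing)
  expect_identical(d1$subject_id, "t")
  expect_true(all(d1$voxels >= -1000 & d1$voxels <= 1000))
  bad <- ct_volume(array(0, c(15, 15, 1)))
  expect_error(denoise_volume(b, bad), "divisible")
})
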