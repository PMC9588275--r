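#' Training configuration for the cycle GAN
#'
#' Collects the optimisation hyperparameters. The defaults are the
#' reference schedule of the method: trade-off weight `lambda_cyc = 10`, batch size 1,
#' Adam with a shared initial learning rate of 2e-4 for generators and
#' discriminators, decayed by a factor 0.8 every 10 epochs, 100 epochs
#' with checkpoints every 25, slice-paired sampling on, and no early
#' stopping. `steps_per_epoch = NULL` uses one step per low-dose training
#' slice.
#'
#' @param lambda_cyc trade-off weight between adversarial and perceptual
#'   cycle-consistency loss.
#' @param lambda_idt weight of an optional identity-mapping term
#'   (`G_LH(x_h) ~ x_h` and `G_HL(x_l) ~ x_l`, measured with the same
#'   perceptual distance). 0 disables it (the method's original objective). Cycle
#'   consistency alone cannot pin absolute intensities — a level shift
#'   introduced by one generator and undone by the other is free, and
#'   patch discriminators with instance normalisation are nearly blind to
#'   it — so short training schedules can drift in HU level; the identity
#'   term anchors each generator to preserve what is already in its target
#'   domain.
#' @param batch_size images per step (the method is defined for 1).
#' @param lr_init initial Adam learning rate (shared by D and G).
#' @param lr_decay multiplicative decay factor.
#' @param lr_decay_every epochs between decays.
#' @param n_epochs total epochs; `checkpoint_every` must divide it.
#' @param checkpoint_every epochs between persisted checkpoints.
#' @param slice_paired use the slice-paired sampler (`FALSE` = ablation).
#' @param steps_per_epoch optional override of steps per epoch.
#' @param d_update_every update the discriminators only every k-th step
#'   (k = 1 is plain alternating updates). Short schedules can need k = 2:
#'   the discriminators' task (spotting residual noise) is easier than the
#'   generators' (removing it), and a discriminator that runs away starves
#'   the generators of useful gradients.
#' @param d_warmup_epochs train the discriminators alone for this many
#'   initial epochs before any generator update. Until a discriminator can
#'   actually tell the two domains apart its scores carry no information,
#'   and adversarial "gradients" from a chance-level discriminator are pure
#'   noise that (under Adam's per-parameter step normalisation) walks the
#'   generators randomly away from their near-identity start. 0 disables
#'   the warm-up.
#' @param adam_beta1,adam_beta2 Adam moment decays.
#' @param seed RNG seed governing sampling and initialisation during
#'   training.
#' @return An object of class `training_config`.
#' @export
training_config <- function(lambda_cyc = 10, lambda_idt = 0, batch_size = 1L,
                            lr_init = 2e-4,
                            lr_decay = 0.8, lr_decay_every = 10L,
                            n_epochs = 100L, checkpoint_every = 25L,
                            slice_paired = TRUE, steps_per_epoch = NULL,
                            d_update_every = 1L, d_warmup_epochs = 0L,
                            adam_beta1 = 0.5, adam_beta2 = 0.999, seed = 1L) {
  vals <- c(batch_size = batch_size, lr_init = lr_init, lr_decay = lr_decay,
            lr_decay_every = lr_decay_every, n_epochs = n_epochs,
            checkpoint_every = checkpoint_every)
  if (any(vals <= 0)) {
    stopf("non-positive config value: %s",
          paste(names(vals)[vals <= 0], collapse = ", "))
  }
  if (lambda_cyc < 0) stopf("`lambda_cyc` must be >= 0")
  if (lambda_idt < 0) stopf("`lambda_idt` must be >= 0")
  if (n_epochs %% checkpoint_every != 0) {
    stopf("`checkpoint_every` (%d) must divide `n_epochs` (%d)",
          checkpoint_every, n_epochs)
  }
  structure(list(lambda_cyc = lambda_cyc, lambda_idt = lambda_idt,
                 batch_size = as.integer(batch_size),
                 lr_init = lr_init, lr_decay = lr_decay,
                 lr_decay_every = as.integer(lr_decay_every),
                 n_epochs = as.integer(n_epochs),
                 checkpoint_every = as.integer(checkpoint_every),
                 slice_paired = isTRUE(slice_paired),
                 steps_per_epoch = steps_per_epoch,
                 d_update_every = as.integer(d_update_every),
                 d_warmup_epochs = as.integer(d_warmup_epochs),
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Learning-rate schedule
#'
#' `lr(epoch) = lr_init * lr_decay^floor(epoch / lr_decay_every)` for a
#' zero-based epoch index: with the defaults, 2e-4 times 0.8 for every 10
#' completed epochs.
#'
#' @param epoch zero-based epoch index (0 = first epoch).
#' @param config a [training_config()].
#' @return Learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, config = training_config()) {
  config$lr_init * config$lr_decay^(floor(epoch / config$lr_decay_every))
}

#' Create an untrained cycle GAN bundle
#'
#' Builds the two generators (low-to-high `G_LH`, high-to-low `G_HL`), the
#' two patch discriminators (`D_H`, `D_L`) and attaches the perceptual
#' feature extractor. Weight initialisation is deterministic for a fixed
#' seed.
#'
#' @param gen_spec a [generator_spec()].
#' @param disc_spec a [discriminator_spec()].
#' @param fx a [feature_extractor()].
#' @param seed RNG seed for weight initialisation.
#' @return An object of class `cycle_gan`.
#' @export
create_cycle_gan <- function(gen_spec = generator_spec(),
                             disc_spec = discriminator_spec(),
                             fx = feature_extractor(), seed = 1L) {
  with_seed(seed, {
    structure(
      list(g_lh = build_generator(gen_spec), g_hl = build_generator(gen_spec),
           d_h = build_discriminator(disc_spec),
           d_l = build_discriminator(disc_spec),
           fx = fx, epoch = 0L,
           loss_history = NULL, seed = as.integer(seed)),
      class = "cycle_gan")
  })
}

#' @export
print.cycle_gan <- function(x, ...) {
  cat(sprintf("<cycle_gan> %d res blocks, %d conv layers per generator, %s perceptual backend, trained %d epochs\n",
              x$g_lh$spec$n_res_blocks, conv_layers_total(x$g_lh$spec),
              x$fx$backend, x$epoch))
  invisible(x)
}

# BCE discriminator loss and gradient w.r.t. scores for one batch of patch
# scores: maximise log(real) + log(1 - fake) <=> minimise the negative.
disc_loss_grads <- function(real_scores, fake_scores, eps = 1e-8) {
  np <- length(real_scores)
  r <- clamp(real_scores, eps, 1 - eps)
  f <- clamp(fake_scores, eps, 1 - eps)
  loss <- -(mean(log(r)) + mean(log(1 - f)))
  d_real <- -1 / (np * r)
  d_fake <- 1 / (length(fake_scores) * (1 - f))
  list(loss = loss, d_real = d_real, d_fake = d_fake)
}

#' Train a cycle GAN on unpaired cohorts
#'
#' Alternating discriminator/generator updates on the combined objective
#' (adversarial + `lambda_cyc` times the perceptual cycle-consistency
#' loss), with the slice-paired (or independent) sampler, the decayed
#' Adam schedule, per-step loss records, and checkpoints every
#' `checkpoint_every` epochs. Inputs must already be normalised to
#' \[0, 1\] (see [normalize_hu()]). Training aborts with an informative
#' error if any loss term becomes non-finite. Fully reproducible for a
#' fixed config seed under single-threaded execution.
#'
#' @param bundle a [create_cycle_gan()] bundle.
#' @param low_cohort,high_cohort lists of normalised [ct_volume()]s.
#' @param config a [training_config()].
#' @param checkpoint_dir directory for checkpoint files (created if
#'   needed); `NULL` disables persistence.
#' @param verbose print a line per epoch.
#' @return The trained bundle, with `loss_history` (one row per step:
#'   adversarial and cycle terms, discriminator losses, learning rate) and
#'   `checkpoints` (paths written).
#' @export
train_cycle_gan <- function(bundle, low_cohort, high_cohort, config,
                            checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(bundle, "cycle_gan"), inherits(config, "training_config"))
  rng_ok <- vapply(c(low_cohort, high_cohort), function(v) {
    min(v$voxels) >= -1e-6 && max(v$voxels) <= 1 + 1e-6
  }, logical(1))
  if (!all(rng_ok)) {
    stopf("cohort volumes must be normalised to [0, 1] before training (see normalize_hu())")
  }
  steps <- config$steps_per_epoch
  if (is.null(steps)) steps <- sum(vapply(low_cohort, n_slices, integer(1)))
  if (!is.null(checkpoint_dir) &&
      !dir.exists(checkpoint_dir)) {
    dir.create(checkpoint_dir, recursive = TRUE)
  }
  opt <- list(g_lh = adam_init(), g_hl = adam_init(),
              d_h = adam_init(), d_l = adam_init())
  history <- vector("list", config$n_epochs)
  checkpoints <- character(0)
  lam <- config$lambda_cyc
  for (epoch in seq_len(config$n_epochs)) {
    lr <- lr_schedule(epoch - 1L, config)
    batches <- slice_paired_batches(low_cohort, high_cohort, steps,
                                    paired = config$slice_paired,
                                    seed = derive_seed(config$seed, epoch))
    rows <- matrix(NA_real_, steps, 9L)
    for (st in seq_len(steps)) {
      b <- batches[st, ]
      x_l <- get_slice(low_cohort[[b$low_subject]], b$low_slice)
      x_h <- get_slice(high_cohort[[b$high_subject]], b$high_slice)
      dim(x_l) <- c(dim(x_l), 1L)
      dim(x_h) <- c(dim(x_h), 1L)

      # generator forward passes (caches kept for backprop)
      f_lh <- generator_apply(bundle$g_lh, x_l, keep_cache = TRUE)
      f_hl <- generator_apply(bundle$g_hl, x_h, keep_cache = TRUE)
      f_lhl <- generator_apply(bundle$g_hl, f_lh$out, keep_cache = TRUE)
      f_hlh <- generator_apply(bundle$g_lh, f_hl$out, keep_cache = TRUE)

      warmup <- epoch <= config$d_warmup_epochs

      # --- discriminator updates (fakes detached) ---
      upd_d <- function(disc, real, fake, state) {
        fr <- net_forward(disc$layers, real, keep_cache = TRUE)
        ff <- net_forward(disc$layers, fake, keep_cache = TRUE)
        lg <- disc_loss_grads(fr$out, ff$out)
        gr <- net_backward(disc$layers, fr$cache,
                           array(lg$d_real, dim(fr$out)))$grads
        gf <- net_backward(disc$layers, ff$cache,
                           array(lg$d_fake, dim(ff$out)))$grads
        stp <- adam_step(disc$layers, grads_add(gr, gf), state, lr,
                         config$adam_beta1, config$adam_beta2)
        disc$layers <- stp$layers
        list(disc = disc, state = stp$state, loss = lg$loss)
      }
      if (warmup || (st - 1L) %% config$d_update_every == 0L) {
        rh <- upd_d(bundle$d_h, x_h, f_lh$out, opt$d_h)
        bundle$d_h <- rh$disc; opt$d_h <- rh$state
        rl <- upd_d(bundle$d_l, x_l, f_hl$out, opt$d_l)
        bundle$d_l <- rl$disc; opt$d_l <- rl$state
      } else {
        # scores recorded without an update, for a continuous loss trace
        sc_h <- net_forward(bundle$d_h$layers, x_h, keep_cache = FALSE)$out
        sf_h <- net_forward(bundle$d_h$layers, f_lh$out, keep_cache = FALSE)$out
        rh <- list(loss = disc_loss_grads(sc_h, sf_h)$loss)
        sc_l <- net_forward(bundle$d_l$layers, x_l, keep_cache = FALSE)$out
        sf_l <- net_forward(bundle$d_l$layers, f_hl$out, keep_cache = FALSE)$out
        rl <- list(loss = disc_loss_grads(sc_l, sf_l)$loss)
      }

      if (warmup) {
        # discriminator warm-up: generators untouched; record the loss
        # terms from forward passes only
        a_h <- list(score = net_forward(bundle$d_h$layers, f_lh$out,
                                        keep_cache = FALSE)$out)
        a_l <- list(score = net_forward(bundle$d_l$layers, f_hl$out,
                                        keep_cache = FALSE)$out)
        p1 <- list(loss = perceptual_cycle_loss(f_lhl$out, x_l, bundle$fx))
        p2 <- list(loss = perceptual_cycle_loss(f_hlh$out, x_h, bundle$fx))
        idt1 <- idt2 <- 0
      } else {
      # --- generator update on the combined objective ---
      # adversarial parts: non-saturating surrogate -log D(fake); gradients
      # flow through D into the fakes, D weights are left untouched
      adv_grad <- function(disc, fake) {
        ff <- net_forward(disc$layers, fake, keep_cache = TRUE)
        s <- clamp(ff$out, 1e-8, 1 - 1e-8)
        gscore <- array(-1 / (length(s) * s), dim(s))
        list(score = ff$out,
             dx = net_backward(disc$layers, ff$cache, gscore,
                               want_grads = FALSE)$dx)
      }
      a_h <- adv_grad(bundle$d_h, f_lh$out)
      a_l <- adv_grad(bundle$d_l, f_hl$out)

      # perceptual cycle terms and gradients at the reconstructions
      p1 <- perceptual_loss_grad(f_lhl$out, x_l, bundle$fx)
      p2 <- perceptual_loss_grad(f_hlh$out, x_h, bundle$fx)

      # backprop cycle 1: x_l -> G_LH -> G_HL; cycle 2: x_h -> G_HL -> G_LH
      b_hl_cyc1 <- net_backward(bundle$g_hl$layers, f_lhl$cache,
                                grads_scale(p1$grad, lam))
      b_lh_cyc2 <- net_backward(bundle$g_lh$layers, f_hlh$cache,
                                grads_scale(p2$grad, lam))
      d_xlh <- a_h$dx + b_hl_cyc1$dx
      d_xhl <- a_l$dx + b_lh_cyc2$dx
      b_lh_main <- net_backward(bundle$g_lh$layers, f_lh$cache, d_xlh)
      b_hl_main <- net_backward(bundle$g_hl$layers, f_hl$cache, d_xhl)
      g_lh_grads <- grads_add(b_lh_main$grads, b_lh_cyc2$grads)
      g_hl_grads <- grads_add(b_hl_main$grads, b_hl_cyc1$grads)

      # optional identity anchoring: each generator should leave members of
      # its own target domain unchanged
      idt1 <- idt2 <- 0
      if (config$lambda_idt > 0) {
        f_ih <- generator_apply(bundle$g_lh, x_h, keep_cache = TRUE)
        p_ih <- perceptual_loss_grad(f_ih$out, x_h, bundle$fx)
        g_lh_grads <- grads_add(
          g_lh_grads,
          net_backward(bundle$g_lh$layers, f_ih$cache,
                       grads_scale(p_ih$grad, config$lambda_idt))$grads)
        f_il <- generator_apply(bundle$g_hl, x_l, keep_cache = TRUE)
        p_il <- perceptual_loss_grad(f_il$out, x_l, bundle$fx)
        g_hl_grads <- grads_add(
          g_hl_grads,
          net_backward(bundle$g_hl$layers, f_il$cache,
                       grads_scale(p_il$grad, config$lambda_idt))$grads)
        idt1 <- p_ih$loss
        idt2 <- p_il$loss
      }

      stp <- adam_step(bundle$g_lh$layers, g_lh_grads, opt$g_lh, lr,
                       config$adam_beta1, config$adam_beta2)
      bundle$g_lh$layers <- stp$layers; opt$g_lh <- stp$state
      stp <- adam_step(bundle$g_hl$layers, g_hl_grads, opt$g_hl, lr,
                       config$adam_beta1, config$adam_beta2)
      bundle$g_hl$layers <- stp$layers; opt$g_hl <- stp$state
      }

      # generator-side adversarial values (non-saturating form, current D)
      adv1 <- mean(log(clamp(a_h$score, 1e-9, 1 - 1e-9)))
      adv2 <- mean(log(clamp(a_l$score, 1e-9, 1 - 1e-9)))
      vals <- c(adv1, adv2, p1$loss, p2$loss, rh$loss, rl$loss, lr, idt1, idt2)
      if (!all(is.finite(vals))) {
        stopf("non-finite loss at epoch %d step %d (adv1=%.3g adv2=%.3g cyc1=%.3g cyc2=%.3g dH=%.3g dL=%.3g)",
              epoch, st, vals[1], vals[2], vals[3], vals[4], vals[5], vals[6])
      }
      rows[st, ] <- vals
    }
    hist_e <- as.data.frame(rows)
    names(hist_e) <- c("adv1", "adv2", "cyc1", "cyc2", "d_h_loss", "d_l_loss",
                       "lr", "idt1", "idt2")
    hist_e$epoch <- epoch
    hist_e$step <- seq_len(steps)
    history[[epoch]] <- hist_e
    bundle$epoch <- epoch
    if (verbose) {
      message(sprintf("epoch %3d/%d  lr %.2e  cyc %.4f  dH %.3f  dL %.3f",
                      epoch, config$n_epochs, lr,
                      mean(hist_e$cyc1 + hist_e$cyc2),
                      mean(hist_e$d_h_loss), mean(hist_e$d_l_loss)))
    }
    if (epoch %% config$checkpoint_every == 0L && !is.null(checkpoint_dir)) {
      bundle$loss_history <- do.call(rbind, history[seq_len(epoch)])
      path <- file.path(checkpoint_dir, sprintf("ckpt_epoch_%03d.rds", epoch))
      saveRDS(list(bundle = bundle, config = config, epoch = epoch), path)
      checkpoints <- c(checkpoints, path)
    }
  }
  bundle$loss_history <- do.call(rbind, history)
  bundle$checkpoints <- checkpoints
  bundle
}

#' Load a training checkpoint
#'
#' @param path checkpoint file written by [train_cycle_gan()].
#' @return A list with elements `bundle`, `config` and `epoch`.
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Denoise a CT volume with a trained cycle GAN
#'
#' Runs every slice through normalisation, the low-to-high generator and
#' denormalisation. Spacing, subject id and slice order are preserved;
#' output HU values lie within the normalisation bounds. Inference is
#' deterministic.
#'
#' @param bundle a trained [create_cycle_gan()] bundle.
#' @param volume a [ct_volume()] in HU.
#' @param norm_spec a [normalization_spec()].
#' @return A denoised [ct_volume()].
#' @export
denoise_volume <- function(bundle, volume, norm_spec = normalization_spec()) {
  stopifnot(inherits(bundle, "cycle_gan"), inherits(volume, "ct_volume"))
  d <- dim(volume$voxels)
  out <- array(0, d)
  for (iz in seq_len(d[3])) {
    x <- normalize_hu(volume$voxels[, , iz], norm_spec)
    dim(x) <- c(d[1], d[2], 1L)
    y <- generator_apply(bundle$g_lh, x, keep_cache = FALSE)$out
    out[, , iz] <- denormalize_hu(clamp(y[, , 1], 0, 1), norm_spec)
  }
  ct_volume(out, spacing = volume$spacing, subject_id = volume$subject_id)
}
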