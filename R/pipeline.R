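#' Experiment configuration
#'
#' One object fully determines an experiment run: phantom specifications
#' for the two cohorts, the dose preset applied to the low-dose cohort,
#' cohort sizes, network and training settings, the radiomics extraction
#' configuration and a global seed. Every artifact written by
#' [run_experiment()] carries the MD5 hash of the serialised
#' configuration.
#'
#' @param spec_low,spec_high phantom specs for the two cohorts (may differ
#'   only in seed and `body_scale`).
#' @param dose a [dose_sim_config()] or [dose_preset()].
#' @param n_train_low,n_test_low,n_high cohort sizes: low-dose training
#'   subjects, held-out low-dose subjects, clean high-dose subjects.
#' @param gen_spec,disc_spec network specifications.
#' @param train a [training_config()].
#' @param extraction an [extraction_config()].
#' @param fx_seed seed of the perceptual backend.
#' @param seed global seed (initialisation etc.).
#' @param save_volumes write cohort and denoised volumes as NIfTI.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(spec_low = phantom_spec(n_slices = 4L,
                                                      seed = 101L),
                              spec_high = phantom_spec(n_slices = 4L,
                                                       seed = 202L),
                              dose = dose_sim_config(incident_intensity = 150),
                              n_train_low = 20L, n_test_low = 10L,
                              n_high = 20L,
                              gen_spec = generator_spec(n_res_blocks = 1L,
                                                        base_channels = 8L,
                                                        n_down = 1L),
                              disc_spec = discriminator_spec(n_layers = 2L,
                                                             base_channels = 16L),
                              train = training_config(n_epochs = 30L,
                                                      checkpoint_every = 15L,
                                                      lr_init = 1e-3,
                                                      lambda_idt = 5,
                                                      d_update_every = 2L,
                                                      d_warmup_epochs = 2L),
                              extraction = extraction_config(
                                feature_classes = c("firstorder", "glcm")),
                              fx_seed = 17L, seed = 1L,
                              save_volumes = FALSE) {
  structure(list(spec_low = spec_low, spec_high = spec_high, dose = dose,
                 n_train_low = as.integer(n_train_low),
                 n_test_low = as.integer(n_test_low),
                 n_high = as.integer(n_high),
                 gen_spec = gen_spec, disc_spec = disc_spec, train = train,
                 extraction = extraction, fx_seed = as.integer(fx_seed),
                 seed = as.integer(seed), save_volumes = isTRUE(save_volumes)),
            class = "experiment_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp)
  unname(tools::md5sum(tmp))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full desk-scale experiment
#'
#' Simulate unpaired cohorts, train the cycle GAN, denoise the held-out
#' low-dose subjects at every checkpoint, extract radiomic features from
#' clean / noisy / denoised volumes, and evaluate image metrics and
#' feature reproducibility (CCC) per checkpoint. All artifacts are written
#' under `out_dir`: the configuration (with hash), checkpoints, feature
#' tables (CSV), CCC reports and a machine-readable `summary.json`.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory (created; must not contain a previous
#'   summary).
#' @param verbose print progress.
#' @return Invisibly, the summary list (also written as JSON): baseline
#'   noisy metrics and per-checkpoint denoised metrics, each with RMSE,
#'   perceptual distance, SNR, mean CCC with CI, and category fractions.
#' @export
run_experiment <- function(config, out_dir = tempfile("cyclect_run_"),
                           verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  saveRDS(config, file.path(out_dir, "experiment_config.rds"))
  norm <- normalization_spec()
  fx <- feature_extractor(seed = config$fx_seed)

  cohorts <- run_stage("cohorts", {
    spec_test <- config$spec_low
    spec_test$seed <- derive_seed(config$spec_low$seed, 999L)
    train_c <- make_unpaired_cohorts(config$spec_low, config$spec_high,
                                     config$dose,
                                     n_low = config$n_train_low,
                                     n_high = config$n_high)
    test_cfg <- config$dose
    test_cfg$noise_seed <- derive_seed(config$dose$noise_seed, 777L)
    test_c <- make_unpaired_cohorts(spec_test, config$spec_high, test_cfg,
                                    n_low = config$n_test_low, n_high = 1L)
    for (i in seq_along(test_c$low)) {
      test_c$low[[i]]$subject_id <- sprintf("test%02d", i)
      test_c$clean_low[[i]]$subject_id <- sprintf("test%02d", i)
    }
    list(train = train_c, test = test_c)
  })
  if (config$save_volumes) {
    vdir <- file.path(out_dir, "cohorts")
    dir.create(vdir, showWarnings = FALSE)
    for (v in c(cohorts$train$low, cohorts$train$high, cohorts$test$low,
                cohorts$test$clean_low)) {
      write_volume(v, file.path(vdir, paste0(v$subject_id, ".nii.gz")))
    }
  }

  bundle <- run_stage("train", {
    b <- create_cycle_gan(config$gen_spec, config$disc_spec, fx,
                          seed = config$seed)
    train_cycle_gan(b,
                    lapply(cohorts$train$low, normalize_hu, spec = norm),
                    lapply(cohorts$train$high, normalize_hu, spec = norm),
                    config$train,
                    checkpoint_dir = file.path(out_dir, "checkpoints"),
                    verbose = verbose)
  })
  utils::write.csv(bundle$loss_history,
                   file.path(out_dir, "loss_history.csv"), row.names = FALSE)

  eval_res <- run_stage("evaluate", {
    clean <- cohorts$test$clean_low
    noisy <- cohorts$test$low
    masks <- cohorts$test$masks_low
    fo_cfg <- config$extraction
    feat_clean <- extract_feature_table(clean, masks, fo_cfg)
    feat_noisy <- extract_feature_table(noisy, masks, fo_cfg)
    pair_mean <- function(as, bs) {
      m <- lapply(seq_along(as), function(i) {
        image_pair_metrics(as[[i]], bs[[i]], fx, norm)
      })
      list(rmse = mean(vapply(m, `[[`, numeric(1), "rmse")),
           perceptual = mean(vapply(m, `[[`, numeric(1), "perceptual")),
           snr_db = mean(vapply(m, `[[`, numeric(1), "snr_db")))
    }
    ccc_summary <- function(tab) {
      v <- tab$ccc
      ci <- mean_ccc_ci(v, seed = config$seed)
      list(mean_ccc = unname(ci["mean"]), ci95 = unname(ci[c("lo", "hi")]),
           categories = as.list(categorize_ccc(v)))
    }
    base_tab <- ccc_table(feat_clean, feat_noisy)
    baseline <- c(pair_mean(clean, noisy), ccc_summary(base_tab))
    utils::write.csv(feat_clean, file.path(out_dir, "features_clean.csv"),
                     row.names = FALSE)
    utils::write.csv(feat_noisy, file.path(out_dir, "features_noisy.csv"),
                     row.names = FALSE)
    utils::write.csv(base_tab, file.path(out_dir, "ccc_noisy.csv"),
                     row.names = FALSE)
    ckpts <- list()
    for (path in bundle$checkpoints) {
      ck <- load_checkpoint(path)
      tag <- sprintf("epoch_%03d", ck$epoch)
      den <- lapply(noisy, denoise_volume, bundle = ck$bundle,
                    norm_spec = norm)
      feat_den <- extract_feature_table(den, masks, fo_cfg)
      tab <- ccc_table(feat_clean, feat_den)
      utils::write.csv(feat_den,
                       file.path(out_dir, sprintf("features_denoised_%s.csv", tag)),
                       row.names = FALSE)
      utils::write.csv(tab, file.path(out_dir, sprintf("ccc_%s.csv", tag)),
                       row.names = FALSE)
      if (config$save_volumes) {
        ddir <- file.path(out_dir, paste0("denoised_", tag))
        dir.create(ddir, showWarnings = FALSE)
        for (v in den) {
          write_volume(v, file.path(ddir, paste0(v$subject_id, ".nii.gz")))
        }
      }
      ckpts[[tag]] <- c(pair_mean(clean, den), ccc_summary(tab),
                        list(epoch = ck$epoch))
    }
    list(baseline_noisy = baseline, checkpoints = ckpts)
  })

  summary <- list(
    config_hash = hash,
    slice_paired = config$train$slice_paired,
    n_train_low = config$n_train_low, n_test_low = config$n_test_low,
    n_high = config$n_high,
    baseline_noisy = eval_res$baseline_noisy,
    checkpoints = eval_res$checkpoints
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(structure(summary, out_dir = out_dir))
}

#' Compare completed experiment runs
#'
#' Reads the per-feature CCC tables of two or more completed runs and
#' compares their distributions per checkpoint with the two-sided Wilcoxon
#' rank-sum test, alongside the image metrics of each run (one row per
#' run and checkpoint).
#'
#' @param run_dirs character vector of [run_experiment()] output
#'   directories (>= 2).
#' @param out optional path for a JSON report.
#' @return A list with `table` (metrics per run/checkpoint) and
#'   `comparisons` (pairwise rank-sum results on the final checkpoint CCC
#'   distributions, plus per-checkpoint p-values for run pairs).
#' @export
compare_runs <- function(run_dirs, out = NULL) {
  if (length(run_dirs) < 2L) stopf("need at least two runs to compare")
  runs <- lapply(run_dirs, function(d) {
    sf <- file.path(d, "summary.json")
    if (!file.exists(sf)) stopf("no summary.json in %s (incomplete run?)", d)
    s <- jsonlite::read_json(sf, simplifyVector = TRUE)
    cccs <- list()
    for (tag in names(s$checkpoints)) {
      cf <- file.path(d, sprintf("ccc_%s.csv", tag))
      cccs[[tag]] <- utils::read.csv(cf)
    }
    list(dir = d, summary = s, cccs = cccs)
  })
  feats <- lapply(runs, function(r) sort(r$cccs[[length(r$cccs)]]$feature))
  for (i in seq_along(feats)[-1]) {
    if (!identical(feats[[1]], feats[[i]])) {
      stopf("feature manifests differ between %s and %s",
            run_dirs[1], run_dirs[i])
    }
  }
  rows <- do.call(rbind, lapply(runs, function(r) {
    do.call(rbind, lapply(names(r$summary$checkpoints), function(tag) {
      ck <- r$summary$checkpoints[[tag]]
      data.frame(run = r$dir, checkpoint = tag,
                 slice_paired = r$summary$slice_paired,
                 rmse = ck$rmse, perceptual = ck$perceptual,
                 snr_db = ck$snr_db, mean_ccc = ck$mean_ccc,
                 ccc_lo = ck$ci95[1], ccc_hi = ck$ci95[2],
                 poor = ck$categories$poor, medium = ck$categories$medium,
                 good = ck$categories$good)
    }))
  }))
  comparisons <- list()
  for (i in seq_along(runs)) {
    for (j in seq_along(runs)) {
      if (j <= i) next
      shared <- intersect(names(runs[[i]]$cccs), names(runs[[j]]$cccs))
      per_ck <- lapply(shared, function(tag) {
        compare_ccc_distributions(runs[[i]]$cccs[[tag]]$ccc,
                                  runs[[j]]$cccs[[tag]]$ccc)
      })
      names(per_ck) <- shared
      comparisons[[sprintf("%d_vs_%d", i, j)]] <-
        list(run_a = runs[[i]]$dir, run_b = runs[[j]]$dir,
             checkpoints = per_ck)
    }
  }
  res <- list(table = rows, comparisons = comparisons)
  if (!is.null(out)) {
    jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  res
}
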