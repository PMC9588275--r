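# cyclect

Unpaired low-dose CT denoising with a cycle-consistent GAN and the full
radiomics-reproducibility evaluation stack around it, in pure R (with
compiled kernels) and runnable on a single CPU with no external data.

## Who this is for

Researchers studying how image quality affects **radiomics** — the
quantitative shape, intensity-histogram and texture features extracted from
a tumour ROI. Quantum noise in low-dose CT destabilises these features;
`cyclect` implements (i) a physics-based dose simulator, (ii) an unpaired
cycle-GAN denoiser with a perceptual cycle-consistency loss and a
slice-paired sampling strategy, and (iii) the statistics used to judge
whether denoising restores feature reproducibility.

## The method in brief

Two generators map between the low-dose domain *L* and high-dose domain
*H*; two patch discriminators judge domain membership. The objective is

```
min_G max_D  L_adv(G, D) + λ · L_cyc(G),          λ = 10
L_adv1 = E[log D_H(x_h)] + E[log(1 − D_H(G_LH(x_l)))]
L_cyc1 = E[ (1/(w·e·d)) · ‖F(G_HL(G_LH(x_l))) − F(x_l)‖² ]
```

where `F` extracts deep feature maps (a VGG-16 `conv2_1`-like map; the
default backend is a fixed, seeded random convolutional extractor so the
package runs offline). Training pairs are drawn **slice-paired**: both
domains contribute the same normalised slice position, exploiting the
apex-to-base anatomy gradient of chest CT. Dose reduction is simulated in
projection space: parallel-beam forward projection with finite detector
aperture, Poisson photon noise at a configurable incident intensity
(presets `low_noise` = 1e5, `high_noise` = 1e4 photons/bin), and filtered
back projection with a Hann-apodised ramp kernel.

Reproducibility is quantified per feature with Lin's concordance
correlation coefficient (CCC), binned as poor (< 0.65), medium
(0.65–0.85) and good (≥ 0.85), with bootstrap CIs on the mean CCC and
Wilcoxon rank-sum comparisons between models.

## Worked example

A desk-scale run of the whole pipeline — simulate unpaired cohorts, train,
denoise held-out subjects, extract features, evaluate CCC:

```r
library(cyclect)

cfg <- experiment_config(seed = 1)   # 64x64 phantoms, 20 train / 10 test
res <- run_experiment(cfg, out_dir = "run_paired")

res$baseline_noisy$rmse        # 0.0275  RMSE of noisy vs reference (held out)
res$baseline_noisy$snr_db      # 19.6    dB
res$baseline_noisy$mean_ccc    # 0.346   mean feature CCC before denoising
final <- res$checkpoints$epoch_030
final$rmse                     # 0.0210  RMSE after denoising
final$snr_db                   # 21.9    dB
final$mean_ccc                 # 0.382   mean feature CCC after denoising
final$perceptual               # 0.102   vs 0.170 noisy
```

Interpretation: after 30 epochs the denoiser reduces held-out RMSE by
~24%, gains ~2.3 dB SNR, roughly halves the perceptual distance, and
lifts the mean CCC of first-order + GLCM features — the same *direction*
of improvement reported for the method at clinical scale (where means
move from ≈0.87 to ≈0.93); desk-scale magnitudes are not comparable to
clinical ones. An ablation run (`cfg$train$slice_paired <- FALSE`) and
`compare_runs()` reproduce the paired-vs-unpaired rank-sum comparison.

Individual stages are exported on their own: `generate_phantom()`,
`simulate_low_dose()`, `train_cycle_gan()`, `denoise_volume()`,
`extract_feature_table()`, `ccc_table()`, `mean_ccc_ci()`,
`compare_ccc_distributions()`. A thin CLI lives at `inst/cli/cyclect.R`
(`simulate`, `run`, `compare`, `denoise`, `extract`, `evaluate`).

## Package layout

- `R/phantom.R`, `R/projection.R`, `R/cohorts.R` — synthetic chest phantoms
  and sinogram-domain dose simulation.
- `R/nn-core.R`, `R/nn-models.R`, `src/` — compiled CNN engine
  (convolution forward/backward, instance norm, Adam) and the
  generator/discriminator builders.
- `R/losses.R`, `R/perceptual.R`, `R/sampler.R`, `R/train.R` — losses,
  perceptual backend, slice-paired sampler, training loop, denoising.
- `R/radiomics*.R` — isotropic resampling, discretisation, first-order,
  GLCM and shape features, 103-feature manifest.
- `R/metrics.R` — RMSE, SNR, CCC, category binning, bootstrap CI,
  rank-sum, CDFs.
- `R/pipeline.R` — `run_experiment()` / `compare_runs()` orchestration.
- `vignettes/methods.Rmd` — model, assumptions, parameter choices and
  limitations.
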