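---
title: "Cycle-GAN low-dose CT denoising and radiomics reproducibility: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cycle-GAN low-dose CT denoising and radiomics reproducibility: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cyclect)
```

## The problem

Low-dose CT trades radiation exposure for quantum noise. That noise does not
just degrade images visually: it destabilises radiomic features — the
quantitative shape, histogram and texture descriptors extracted from a tumour
ROI — and with them any downstream model built on those features. `cyclect`
implements an unpaired denoising approach for this setting and the complete
evaluation stack it is judged by, so that the whole chain (dose simulation →
denoising → feature extraction → reproducibility statistics) runs on
synthetic phantoms with no external data.

Unpaired matters: matched low-dose/full-dose scan pairs of the same patient
rarely exist. A cycle-consistent GAN learns the mapping between the two
image domains from *cohorts* rather than pairs: a generator `G_LH` maps
low-dose to high-dose (the denoiser), a second generator `G_HL` maps back,
and two patch discriminators `D_H`, `D_L` judge whether an image looks like
a member of each domain.

## Losses

For the low-to-high direction the adversarial value is the usual GAN
objective

    L_adv1 = E[log D_H(x_h)] + E[log(1 - D_H(G_LH(x_l)))],

maximised by the discriminator and minimised by the generator (symmetrically
for the other direction; `adversarial_loss()` computes this value from
score batches). For generator updates the training loop uses the standard
non-saturating surrogate `-log D(G(x))`, which has the same fixed points but
much better gradients early in training when the discriminator wins easily;
this is the conventional implementation choice for this loss family.

The cycle-consistency term replaces the usual pixelwise error with a
*perceptual* distance computed on feature maps:

    L_cyc1 = E[ (1 / (w·e·d)) · || F(G_HL(G_LH(x_l))) - F(x_l) ||^2 ],

where `F` is a fixed convolutional feature extractor applied after the
single CT channel is triplicated to RGB, and `w`, `e`, `d` are the feature
map dimensions. The rationale: a reverse generator can re-create plausible
noise *texture* but never the exact noise *realisation*, so a pixelwise
cycle penalty punishes exactly the thing denoising must do. A feature-space
distance at reduced resolution is insensitive to the specific noise draw
while still anchoring anatomy.

The combined objective is `L_adv + λ·L_cyc` with `λ = 10`
(`total_objective()`), optimised with Adam at a shared learning rate for
generators and discriminators, decayed ×0.8 every 10 epochs from 2e-4, batch
size 1, checkpoints every 25 epochs of a 100-epoch schedule, and no early
stopping (`training_config()` defaults). Desk-scale runs use the same
machinery with a shorter schedule (below).

### The perceptual backend

The method's original formulation uses an ImageNet-pretrained VGG-16
`conv2_1` feature map. Pretrained VGG weights are an external binary artifact; this
package therefore defines a `feature_extractor()` abstraction with two
backends:

* `seeded_random_conv` (default): a fixed, seeded two-stage random
  convolutional network (3×3 conv → ReLU → 2×2 average pool → 3×3 conv →
  ReLU) whose output lives at half resolution, matching the resolution and
  role of `conv2_1`. Random convolutional projections preserve relative
  distances well (a Johnson–Lindenstrauss-style argument), which is all a
  feature-space *distance* needs; the backend is deterministic, offline and
  recorded in every checkpoint. Its features are scaled (`output_scale`,
  default 10) so that perceptual distances for noisy/denoised CT pairs sit
  in the 0.02–0.2 range conventionally reported with VGG features: the
  trade-off `λ = 10` was balanced against distances on that scale, and
  unit-variance random features would silently weaken the cycle term by
  two orders of magnitude.
* `pretrained_vgg16`: accepts a converted weights file when one is
  available; without one it errors with instructions rather than silently
  substituting.

Inputs are mapped from [0, 1] to [-1, 1] before the backend (its canonical
input scaling), after channel triplication.

### Generator and discriminator layout

Only the coarse architecture of the original networks is fixed (nine
residual blocks, 27 convolutional layers); widths and the discriminator are
config here. `generator_spec()` builds: initial 7×7 convolution, `n_down`
stride-2 downsampling convolutions, `n_res_blocks` residual blocks (two 3×3
convolutions each), `n_down` nearest-neighbour-upsample+3×3 stages, a 3×3
refinement convolution and a 1×1 linear output convolution — so
`conv_layers_total = 2·n_res_blocks + 2·n_down + 3`, which is 27 at the
full-scale configuration (9 blocks, 3 stages). Instance normalisation
follows every convolution except the output layer, because with batch size
1 batch statistics are degenerate. The discriminator is a PatchGAN stack of
stride-2 4×4 convolutions with leaky ReLU; with 3 stride-2 layers its
receptive field is the conventional 70×70.

Two deliberate deviations from the classic translator, both recorded in
`generator_spec()`:

* **Global residual skip** (`global_skip = TRUE`): the generator predicts a
  correction to its input, `G(x) = x + f(x)`, with the output convolution
  initialised essentially at zero. Denoising is a near-identity mapping;
  starting at the identity anchors the perceptual cycle loss from step one
  and lets the adversarial term concentrate on removing the noise texture.
  Without the skip, desk-scale runs spend most of their budget re-learning
  anatomy through the feature-space bottleneck. The flag exists so the
  plain translator can be trained too.
* **No image-history buffer**: not part of the method's description;
  plain alternating updates are used.

Three optional stabilisers for short schedules live in
`training_config()`, all off (or 1) by default so the method's original objective
and update rule are the defaults:

* `lambda_idt` — an identity-mapping term `G_LH(x_h) ≈ x_h`,
  `G_HL(x_l) ≈ x_l` in the same perceptual distance. Cycle consistency
  cannot pin absolute HU levels (a level shift introduced by one generator
  and undone by the other is free, and instance-normalised patch
  discriminators are nearly blind to it), so short runs drift in intensity
  without this anchor. The desk experiment uses `λ_idt = λ/2`, the
  conventional ratio.
* `d_update_every` — update discriminators every k-th step. Their task
  (spotting residual noise) is easier than the generators' (removing it);
  k = 2 keeps the game balanced in short schedules.
* `d_warmup_epochs` — train the discriminators alone first. A chance-level
  discriminator emits pure noise as "gradient", and under Adam's
  per-parameter step normalisation that noise moves the generators as far
  as real signal would, walking them randomly away from the identity
  before any useful signal exists.

### Slice-paired sampling

Chest anatomy varies systematically from apex to base, so two scans are
most similar at the same *relative* slice position. The slice-paired
training strategy (`slice_paired_batches(paired = TRUE)`) draws a random
subject from each cohort and one random slice from the low-dose scan, then
takes the high-dose slice at the same normalised position
`(i-1)/(n-1)`, rounding half-integers down so the first slice always pairs
with the first slice. The ablation mode (`paired = FALSE`) draws both slice
indices independently; for equal-length volumes the chance of an accidental
position match is then `1/n_slices`, a property the tests verify against
the binomial null. Pairing by *normalised* rather than absolute index is
the package's resolution of the unequal-length case, since clinical scans
differ in slice count.

## Dose simulation

Quantum noise arises in projection space, so the simulator works there:

1. `forward_project()` — parallel-beam Radon transform of the slice after a
   linear HU→attenuation mapping (`mu = hu_to_mu_scale · (HU + 1000)`, air
   = 0, water 0.0192/mm), 180 evenly spaced angles over [0, 180) by
   default, bilinear interpolation along rays. Each detector bin averages
   three parallel sub-rays across its width: real detectors integrate the
   beam over a finite aperture, which band-limits the projections and
   spreads reconstructed edges over about one bin. Zero-width rays leave
   tissue boundaries unphysically sharp at coarse bin sizes — sharp enough
   that *no* denoiser, learned or classical, can beat the noisy image in
   RMSE, because any smoothing pays more at edges than it gains in flat
   regions (`n_subrays = 1` restores ideal rays for geometry tests).
2. `inject_quantum_noise()` — transmission Poisson model: `I = I0·exp(-p)`
   per detector bin, `I' ~ Poisson(I)`, counts clamped at ≥1 before the
   log, `p' = -log(I'/I0)`. Unbiased in the transmission domain and
   deterministic per seed. Above 1e7 expected counts the draw switches to
   its Gaussian limit (R's Poisson sampler cannot represent such counts and
   the limit is exact to machine precision there).
3. `reconstruct()` — filtered back projection with the band-limited ramp
   kernel applied via FFT, apodised with a Hann window by default (the
   clinical soft-tissue kernel); `kernel = "ramp"` gives the pure ramp,
   which maximises resolution but amplifies exactly the high-frequency
   noise a soft kernel suppresses.

The incident intensity `I0` is the dose surrogate (proportional to mAs):
presets `low_noise` = 1e5 and `high_noise` = 1e4 photons per bin define the
package's two named noise levels. Reconstruction noise at a fixed photon
count depends on the detector-bin size — a 5.5 mm bin collects ~30× the
photons of a 1 mm bin — so the same `I0` that produces severe noise at
clinical 512²/1 mm geometry is nearly clean at the desk 64² geometry. The
desk-scale experiment therefore calibrates its dose to the *image-domain*
error regime instead: `incident_intensity = 150` under the
aperture-plus-Hann chain yields a noisy-vs-reference RMSE of ≈0.023 on
the [0, 1] scale, a value typical of reported simulated high-noise chest CT studies,
with a visible photon-starvation bias through the thickest paths (counts
clamped at 1 before the log). The exact photon calibration of any
clinical protocol is scanner-specific and is exposed as configuration,
not claimed. Physics the simulator deliberately omits:
scatter, beam hardening, electronic noise, detector cross-talk, helical
geometry, vendor kernels.

Numerical notes: FBP of a discontinuous object carries Gibbs ringing at
edges — the round-trip accuracy test therefore checks the interior and a
smooth phantom (both ≲0.004 RMSE on the [0, 1] scale) rather than the edge
ring itself. Mass conservation across angles holds to 0.1%.

## The synthetic cohorts

`phantom_spec()`/`generate_phantom()` build chest-like slices: an elliptical
soft-tissue body (with mild texture), a bony shell, two lung fields, and
ellipsoidal soft-tissue lesions with seeded internal texture placed wholly
inside the lungs (bounded rejection sampling; failure to place a lesion is
an error, not a silent omission). Body and lung size scale smoothly and
monotonically with slice position, so slice index carries anatomical
information — the property slice pairing exploits. Lesions are drawn as a
heterogeneous population, the way real tumour cohorts are: physical
semi-axes of 16–33 mm, mean attenuation from −150 to +100 HU (solid to
part-solid), and centimetre-scale internal texture of per-lesion strength.
This heterogeneity is not decoration: concordance analysis measures
agreement *relative to between-subject variance*, and a cohort of clone
lesions makes CCC degenerate regardless of image quality. Texture must
also live at a scale the imaging chain can resolve — structure below the
FBP resolution limit is unrecoverable by any denoiser and only rewards
hallucination.

Every cohort member — high-dose and low-dose alike — passes through the
same forward-projection/FBP chain; the high-dose cohort and the evaluation
references are *noise-free reconstructions*, not ideal phantoms. This
mirrors the source setting (low-dose scans simulated by adding sinogram
noise to acquired high-dose scans) and keeps the two GAN domains matched
in resolution: with an idealised sharp reference, the adversarial term
rewards inventing detail beyond the data instead of removing noise.

`make_unpaired_cohorts()` derives disjoint per-subject seeds for the two
domains and optionally a `body_scale` difference, emulating the population-level habitus shift seen
between real cohorts (the failure mode where a GAN learns to "slim" its
patients). The default experiment keeps body scale equal across domains,
matching the simulated-training setting in which both cohorts come
from the same population.

What the phantoms do *not* emulate: real parenchymal texture and vasculature,
respiratory/cardiac motion, metal and beam-hardening artifacts,
scanner-kernel differences. Passing the end-to-end tests therefore shows the
method's machinery works and improves synthetic reproducibility; it does not
certify performance on clinical data.

## Radiomics

`extract_features()` crops to the ROI bounding box, resamples image and mask
to 2 mm isotropic voxels (trilinear / nearest-neighbour), discretises ROI
intensities with a fixed 25 HU bin width, and computes the configured
classes. The manifest (`feature_manifest()`) accounts for 103 features —
13 shape, 17 first-order, 73 texture (22 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM,
5 NGTDM) — with the shape class excluded from reproducibility analysis (90
features) because mask-only features cannot respond to denoising. The
builtin backend implements shape, first-order and a 12-feature GLCM subset
at formula level (symmetric co-occurrence matrices over the 13 unique 3-D
directions at distance 1, features averaged over directions); the full
103-feature extraction is delegated to a pyradiomics adapter when that
library is installed. Formula conventions, chosen once and documented:
population moments, non-excess kurtosis, type-7 quantiles, energy as a
plain sum of squares, entropies in bits.

## Reproducibility statistics

* `rmse()` — root mean squared error on [0, 1]-normalised images.
* `snr_db()` — SNR definition is not standardised; this package uses the
  amplitude ratio `20·log10(||ref|| / ||ref - test||)` and records the
  definition in the result so alternatives can be swapped.
* `ccc()` — Lin's concordance correlation coefficient with population (1/n)
  moments, per the original estimator: penalises mean and scale shifts as
  well as decorrelation.
* `categorize_ccc()` — the conventional bins: poor < 0.65 ≤ medium < 0.85 ≤
  good.
* `mean_ccc_ci()` — the CI method for a mean CCC over features is not
  standardised either; this package uses a seeded percentile bootstrap over
  features (2000 resamples).
* `compare_ccc_distributions()` — two-sided Wilcoxon rank-sum
  (Mann–Whitney) with tie-corrected normal approximation and continuity
  correction; validated in tests against exhaustive enumeration and
  `wilcox.test`.

Degenerate inputs get explicit signals: constant-and-equal CCC inputs return
`NA` with a warning, identical pooled rank-sum samples likewise, single-voxel
first-order regions return zero moments plus a `degenerate` attribute.

## Desk-scale experiment and problem sizes

`run_experiment()` wires everything together: simulate cohorts → train →
denoise held-out subjects at every checkpoint → extract features from
clean/noisy/denoised volumes → CCC reports per checkpoint → `summary.json`.
The default configuration is the package's desk-scale condition: 64×64
phantoms with 4 slices, 20 low-dose training subjects, 10 held-out low-dose
subjects, 20 high-dose subjects, a dose of 150 photons/bin (calibrated to
the high-noise image-error regime under this geometry), a compact
generator (1 residual block, 8 base channels, 1 resolution stage), a
16-channel two-stage patch discriminator, and 30 epochs (2400 batch-1
steps) at `lr = 1e-3` with checkpoints every 15, identity weight λ/2,
discriminator updates every 2nd step after a 2-epoch discriminator
warm-up. Two scheduling choices differ from the full-scale defaults and
are deliberate: the learning rate is larger because the schedule is ~20×
shorter than the full-scale reference schedule (2400 steps vs tens of thousands), and epochs are
capped so a complete run trains in minutes on one CPU core. The
full-scale schedule remains available as `training_config()`'s defaults.

On these conditions the end-to-end expectation — held-out RMSE, SNR and
perceptual distance improve after denoising, and the mean per-feature CCC
of denoised-vs-reference exceeds noisy-vs-reference — is asserted by the
test suite as a *direction*, not a magnitude: desk-scale networks and
cohorts cannot (and should not) reproduce clinical effect sizes. A
representative seed gives RMSE 0.0275 → 0.0210, SNR 19.6 → 21.9 dB,
perceptual 0.170 → 0.102 and mean CCC 0.346 → 0.382 after 30 epochs.

## Known limitations

* The perceptual backend approximates the *role* of VGG features, not their
  values; perceptual-loss magnitudes are not comparable across backends.
* The discriminator/generator widths at desk scale are far below
  clinical-scale capacity; results demonstrate mechanism, not clinical
  quality.
* The simulator's noise calibration is in photons per bin, not mAs; mapping
  to a scanner protocol requires a calibration measurement the package does
  not claim.
* GAN training remains a min-max game: with unlucky seeds or strong domain
  shift between cohorts the generator can drift (the body-scale experiment
  reproduces this failure mode deliberately). The divergence guard aborts
  on non-finite losses rather than continuing silently.
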