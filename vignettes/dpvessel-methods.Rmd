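---
title: "Methods: differentially private synthesis of labeled vessel patches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differentially private synthesis of labeled vessel patches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dpvessel)
```

## Overview

`dpvessel` trains a Wasserstein GAN whose generator emits paired
(image, segmentation-label) patches of angiography-like data, privatizes the
critic's training with DP-SGD, accounts the privacy budget with a Rényi-DP
accountant, and measures what privacy costs in downstream utility by
training U-Nets on the synthetic pairs and scoring them on held-out
volumes. Because clinical angiography cannot be redistributed, the package
ships a phantom generator whose outputs play the role of the patient data
throughout.

This vignette records the model assumptions, the tunable parameters and
their defaults, the numerical choices, and — importantly — what the
phantom-based evaluation can and cannot show.

## The phantom model

`generate_volume()` draws `n_vessels` random-walk centerlines (step 0.5
voxel, directional momentum 0.92, reflecting boundaries), gives each a
smoothly varying radius in [1, 4] voxels, and rasterizes the tube support
exactly: a voxel is a vessel voxel iff its center lies within the local
radius of some centerline point. Intensity is a Gaussian cross-sectional
profile on a noisy background; the vessel core is at least three background
standard deviations above the background mean before noise, and the volume
is min–max normalized to [0, 1]. This reproduces the one statistic that
matters for the task — bright curvilinear tubes on a darker noisy
background, with strong foreground/background imbalance — and deliberately
claims no MRI physics (no acquisition model, no anatomy, no skull).

Defaults: shape 64×64×48 voxels at 0.5 mm spacing, 6 vessels,
background-noise SD 0.08. A volume at these defaults carries a vessel voxel
fraction of roughly 4–8%. Where tests emulate the sparsity of real
time-of-flight angiography (vessel fraction of a few percent at most) they
use 2 vessels per 48×48×32 volume, giving 2–4%.

Patch extraction follows the two-quota scheme: `n_vessel_centered` patches
whose central pixel is a vessel voxel (sampled uniformly over all such
positions) and `n_random` patches uniform over all in-bounds positions.
Patches are axial, cover the half-open window `[r, r+P) × [c, c+P)` in
0-based coordinates with center at `(r + P%/%2, c + P%/%2)`, and every
(subject, slice, row, column) origin is used at most once, enforced by
resampling with a retry cap. Random patches may by chance be
vessel-centered; the sampling is uniform over all positions, and the patch
records its mode. The published protocol's quotas (500 + 500 per subject at
P = 96) are the `paper` profile defaults.

## Privacy machinery

`clip_and_noise()` implements the DP-SGD aggregation: each per-sample
gradient is rescaled by `min(1, C/‖g‖₂)`, the clipped gradients are summed,
Gaussian noise of per-coordinate scale `σC` is added, and the sum is
divided by the batch size. With `σ = 0` the result is the exact clipped
mean (used by the non-private arm, which reports ε = ∞ and never touches
the ledger).

The accountant treats each critic update as a Poisson-subsampled Gaussian
mechanism at rate `q = B/N`. At integer orders α the Rényi divergence bound
is the exact binomial expansion, evaluated in log space; the plain
mechanism has the closed form `α/(2σ²)`. Non-integer orders ≥ 2 are bounded
by linear interpolation of `(α−1)ε(α)` between bracketing integers (valid
by convexity). Composition is exactly additive per order. The default grid
is the integers 2…64, plus a fine grid {1.25, 1.5, 1.75} near 1 exposed for
the unsubsampled mechanism; integer orders are what the subsampled bound
supports exactly, and past 64 the conversion minimum never moves for the
budgets in scope. ε is reported in nats.

Two RDP→(ε, δ) conversions are implemented: the tight form
`ε(α) + log((α−1)/α) − (log δ + log α)/(α−1)` (default) and the classic
`ε(α) + log(1/δ)/(α−1)` used by the accounting engines contemporary with
the original experiments; both minimize over the grid.

**Step-count convention.** Only critic optimizer updates consume budget:
the generator's parameters meet real data only through the critic's
(already privatized) outputs, so its updates are post-processing. What
counts as "one epoch" is genuinely ambiguous in the training recipe this
package reproduces. `train_gan()` adopts one sampled critic batch per step
with `ceiling(N/B)` steps per epoch, the generator updating every
`n_critic`-th step. `account_training_run()` additionally offers the
`per_generator_update` reading — `n_critic` critic updates per generator
iteration, `ceiling(N/B)` generator iterations per epoch — which is the
convention under which the published budget (ε ≈ 7.6 with the classic
conversion over the full 50-epoch run at σ = 0.65) is reproduced. A
checkpoint selected post hoc across epochs is covered only by the full-run
budget, which is why the acceptance script reports that quantity.

## GAN architecture and training

The generator maps a 128-dimensional standard-normal latent through one
linear layer and `n_stages` (nearest-neighbour ×2 upsample + 3×3
convolution + ReLU) stages to a 2-channel P×P output; the output head is
tanh rescaled to [0, 1] for the image channel and a sigmoid for the label
channel, binarized at 0.5 only at synthesis time. The critic downsamples
the 2-channel pair with `n_stages` stride-2 kernel-4 convolutions
(LeakyReLU 0.2) into a single unbounded score. There is deliberately no
batch normalization anywhere in the critic: batch-coupled statistics would
make per-sample gradients ill-defined under DP-SGD. Weight clipping to
±0.01 after every critic step supplies the Lipschitz constraint; the DP
clip (`C = 1`) is a different parameter acting on gradients, not weights.

Training defaults (the `paper` profile): RMSprop at 5e-5 for both networks,
batch 32 sampled uniformly with replacement, 5 critic updates per generator
update, 50 epochs, P = 96. The `desk` profile (P = 32, 20 epochs, slimmer
channels) keeps identical mechanics at CPU scale. RMSprop's running
second-moment state is not noised — only gradients are privatized, matching
the DP-SGD construction. Per-sample gradients are computed from a single
batched forward/backward by slicing each sample's column block out of the
im2col caches; a loop-over-samples oracle in the tests pins the equivalence.

## Segmentation readout

The U-Net is a slim two-down/two-up encoder–decoder with skip
concatenations, trained with soft Dice loss (1 − soft DSC, smoothing 1) —
chosen because Dice matches the selection metric and tolerates the strong
class imbalance; the hyperparameter grid crosses learning rate
{1e-3, 1e-4} × dropout {0, 0.1} × label-consistent augmentation (flips and
transposition) {off, on}, eight configurations in all. Model selection is
by mean volume-level validation DSC (ties: lower bAHD, then order).
Whole-volume inference tiles each axial slice with a regular grid of P×P
patches flush with the far edges, averages per-pixel probabilities over
overlapping tiles, and thresholds at 0.5.

## Metrics

DSC uses the both-empty = 1, one-empty = 0 conventions (the raw formula is
0/0 there). The balanced average Hausdorff distance is implemented exactly
as its defining formula prints it: *both* directed mean nearest-neighbour
sums are normalized by the ground-truth voxel count and averaged. This
makes the metric asymmetric whenever |S| ≠ |G| and very hard on false
positives when |S| ≫ |G| — a property the tests lock in deliberately,
because the conventional variant (second term normalized by |S|) is a
different metric. Distances are in voxels unless a physical spacing is
supplied.

The Fréchet distance between feature Gaussians uses the symmetric
`Tr((Σ₁^{1/2}Σ₂Σ₁^{1/2})^{1/2})` form; eigenvalues below −1e-8 (relative)
raise an error, smaller negatives are clamped to zero. The feature
extractor is a pluggable contract; the default is a fixed-seed random
convolutional embedding (16 unit-norm 7×7 kernels at stride 4, ReLU,
mean and SD pooled per filter — 32 dimensions), with a hand-checkable 8-D
moment extractor as the alternative. Random convolutional features are a
standard lightweight surrogate for pretrained deep embeddings; the Fréchet
arithmetic is agnostic to the choice, and no pretrained weights are
downloaded or shipped.

SSIM defaults to k₁ = 0.01, k₂ = 0.03, L = 1 for [0, 1] images, evaluated
globally by default (sliding windows via integral images are available);
variances use the population convention. The mode-collapse probe averages
SSIM over all unordered pairs (the published protocol uses 1,000 images),
with a seeded pair subsample above a configurable cap.

## Embedding

The t-SNE implementation calibrates per-point bandwidths by bisection to a
Shannon perplexity target (default 30), symmetrizes to
`p_ij = (p_{j|i} + p_{i|j})/2N` where N is the number of points, and
descends the Kullback–Leibler cost with the classic schedule: gain-free
gradient descent with momentum 0.5→0.8 at iteration 250, early
exaggeration ×4 for the first quarter of the iterations, seeded 1e-4
Gaussian initialization, centered each step. The exact KL gradient is
verified against finite differences. The original experiments replaced KL
with "the Wasserstein metric" without defining the object it acts on; the
package's `cost = "wasserstein"` mode minimizes the 1-D Wasserstein
distance between the sorted similarity-value distributions of P and Q — a
genuine Wasserstein metric on those value distributions, clearly labeled an
interpretation — while KL remains the default, reference-verified mode. An
entropic optimal-transport reading over the pair index set was considered
and rejected: it requires a ground metric between index pairs that nothing
defines, and a cost matrix quadratic in N².

## Pipeline and seeds

`plan_experiment()` fixes the cohort split, the arm list of noise
multipliers {0, 2, 1.5, 1.2, 1, 0.8, 0.725, 0.65} (0 encoding ε = ∞, run
once; private arms repeated, 5× at paper scale), and derives every seed any
stage consumes from the master seed through named streams (cohort, patches,
gan, unet, synthesis) with a small multiplicative string hash into 31-bit
space. `run_sweep()` isolates failures per arm and emits a per-run table, a
summary in the shape mean (SD) per metric per arm, and CSV/JSON outputs.

The `desk` profile runs 8/2/3 subjects with 100 + 100 patches each at
P = 32 over 20 GAN epochs with 2 repeats and a 2-configuration U-Net grid.

## Problem sizes used by the test suite

The tests exercise everything at sizes chosen for a single CPU. The
end-to-end trend test uses a micro profile: 3 training and 2 test phantoms
(48×48×32, 2 vessels each, vessel fraction 2–4%), 60 patches per training
subject at P = 16, an 80-epoch WGAN (≈ 480 critic updates) at learning
rate 5e-4 — raised from the paper-scale 5e-5 because a few hundred RMSprop
steps at 5e-5 leave the generator at its initialization — one U-Net
configuration (lr 1e-3, 6 epochs), and noise arms σ ∈ {0, 1, 2} over three
fixed seeds. The miniature sweep test is smaller still (2/1/1 subjects, 3
GAN epochs) and checks plumbing and schemas, not learning.

## What the tests do and do not show

Phantoms share none of the covariate structure of clinical angiography
beyond bright-tube-on-dark-background; passing tests demonstrate that the
machinery is correct (accounting, clipping, losses, metrics, selection,
stitching) and that the expected qualitative privacy-utility trade-off
appears at micro scale — they say nothing quantitative about real MRA
performance. Two scale limitations are worth stating plainly. First, the
published experiments accumulate ~3×10⁵ critic updates per model; the
micro profile accumulates ~5×10². At that budget the non-private arm
learns enough structure for its synthetic pairs to train a better U-Net
than the noise arms' (the ordering σ=0 ≥ σ=1 ≥ σ=2 is asserted in 2 of 3
seeds), but the two private arms are both noise-dominated and barely
distinguishable from one another. Second, the train-versus-test FID gap is
a *memorization* signal: a generator that has taken a few hundred steps has
memorized nothing, so the gap at micro scale is estimation noise and does
not reproduce the full-scale finding that the non-private model sits
closest to its training pool. The corresponding assertion is kept in the
suite at the documented scale rather than weakened.

## Known limitations

- 2-D patches only; no 3-D synthesis or 3-D U-Net.
- Weight-clipped WGAN only (no gradient penalty, no spectral norm), as in
  the recipe being reproduced.
- The Fréchet extractor is not a pretrained network; absolute FID values
  are not comparable to published Inception-based numbers, only contrasts
  within a run are meaningful.
- The accountant covers Poisson/uniform-with-replacement sampling only;
  shuffled minibatches void the amplification theorem and are not offered.
- ε for the published recipe depends on an epoch/step convention the
  original description leaves ambiguous; both readings are implemented and
  the chosen one is documented above.
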