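---
title: "Synthetic lesion generation for segmentation augmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic lesion generation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lesionsynth)
```

`lesionsynth` builds synthetic, labelled lesions in two stages — a
statistical shape model that invents plausible lesion masks, and a
partial-convolution GAN that paints plausible textures into those masks —
and then quantifies both the realism of the result (GLCM feature
distributions) and its practical value (held-out segmentation performance
with and without the synthetic data). This vignette explains each model,
its assumptions, the tunable parameters, and the design decisions taken
where more than one reasonable construction exists.

## The phantom data generator

All development, testing and the bundled study run on a seeded phantom
generator rather than clinical CT. Each phantom slice emulates a windowed,
organ-extracted abdominal CT slice:

* the organ is a smooth star-convex blob (radial cosine-series profile,
  orders ≤ 3, amplitudes ≤ 0.15) covering roughly 20–60 % of the frame;
  pixels outside it are exactly 0, as after contour-based liver extraction;
* organ tissue is a base intensity (≈ 0.45–0.6) plus Gaussian-filtered
  white noise with a correlation length of about 3 px (filter σ = 1.5);
* lesions are star-convex regions (orders ≤ 5, amplitudes ≤ 0.3, tapered
  with order) whose areas are drawn log-uniformly between 15 px and 10 %
  of the organ area — every lesion clears the > 10 px minimum-area filter
  applied to real lesions — with a mean-intensity offset of at least 0.15
  from the surrounding tissue and a shorter noise correlation length
  (σ = 0.5), so that second-order texture statistics genuinely
  distinguish lesion from organ;
* all intensities lie in [0, 1], matching the preprocessing convention
  below, and every slice is bit-reproducible from its seed.

`preprocess_slice()` implements the preprocessing applied to real CT:
a linear [−100, 200] HU soft-tissue window normalised to [0, 1], organ
extraction (outside = 0), and resampling to a square output (bilinear for
intensities, nearest-neighbour for masks so they stay binary). Datasets
are split by synthetic *subject* (about four slices each, sharing a
base-intensity trait), never by slice, in proportions ≈ 52/24/23 %.

What the phantom does **not** model: 3-D anatomy and inter-slice
correlation, partial-volume effects, scanner noise spectra, and contrast
kinetics. Passing tests on phantoms therefore demonstrates correctness of
the algorithms and the direction of the augmentation effect, not clinical
performance.

## The shape model

Lesion masks are converted to shape vectors `[x1..xn, y1..yn]` of
`n = 200` boundary landmarks by default (the bundled desk-scale studies
use 100), equally spaced in arc length along the traced outer boundary,
ordered counter-clockwise from the landmark at the smallest polar angle
about the centroid (ties broken by the smaller row). Two implementation
details matter:

* Boundary tracing visits pixel centres; the landmarks are pushed half a
  pixel outward along the centroid ray so the polygon follows the outer
  pixel edge. Without this, rasterising a shape recovers a systematically
  smaller region (for a disk of radius r the polygon through boundary
  centres has radius ≈ r − 0.5), and the extract → rasterise round trip
  loses ~8 % of the area.
* Generalised Procrustes alignment (centre, unit centroid size, iterated
  rotation-only alignment to the evolving mean, convergence at 1e-8 or
  100 iterations) determines the common frame only up to one global
  rotation, which would otherwise depend on the input order through the
  initial mean. The gauge is fixed by rotating everything so the mean
  shape's first landmark lies on the +x axis; with that convention the
  model is invariant to training-set ordering up to mode signs, and mode
  signs themselves are fixed by making each component's largest-magnitude
  coordinate positive.

PCA is run with explicit mean centring; the mean shape is stored
separately from the 10 orthonormal modes. (A model whose "first
component" is the uncentred average is the other construction in
circulation; centring is standard point-distribution-model practice and
is what this package does.) New shapes are sampled with independent
Gaussian mode weights `w_i ~ N(0, weight_scale² · var_i)` — the weight
distribution is a modelling choice; Gaussians with the empirical mode
variances are the natural default — and resampled (≤ 50 tries) if the
polygon self-intersects.

Placement draws a rotation uniform on [0, 2π) and a target centroid
uniform over organ pixels, rasterises (even-odd rule on pixel centres),
and rejects candidates that leave the organ, touch an existing lesion,
fall to ≤ 10 px, or break into several components. Areas are drawn from
the empirical training-area distribution with multiplicative log-normal
jitter (σ = 0.1) and floored at 11 px.

## The partial-convolution generator

The inpainting generator must not let values inside the lesion hole leak
into its prediction. Partial convolution guarantees this structurally: at
each window, `x' = W'(X ⊙ M) · K/Σ(M) + b` when the window contains any
valid pixel (K = window element count), and exactly 0 — without bias —
otherwise. The `K/Σ(M)` renormalisation makes a fully valid window reduce
*exactly* to the standard convolution; the package treats the alternative
reading (a bare `1/Σ(M)` factor) as a typesetting loss in its source
material, since that version would not reduce to ordinary convolution
anywhere. The paired mask update marks an output pixel valid iff any
input pixel under its kernel was valid — a binary dilation with a square
structuring element — so repeated layers eventually saturate the mask to
all-ones.

The generator is a U-Net with `n_stages` (default 8) encoder stages of
stride-2, kernel-4, padding-1 partial convolutions (ReLU) and `n_stages`
decoder stages of nearest-neighbour 2× upsampling, concatenation of the
same-stage encoder features *and masks*, and a kernel-3 partial
convolution (LeakyReLU 0.2). Batch normalisation is applied to every
convolution except the first and the last; the final layer outputs one
channel through a sigmoid, keeping predictions in [0, 1] like the
normalised inputs. Channel widths double from `base_channels` (default
64) and cap at 8× base — 64, 128, 256, 512, 512, 512, 512, 512 at full
scale. Generator kernel sizes and channel plan are conventional
inpainting choices; they are configurable, and the desk-scale profile
used throughout the tests is 4 stages × 8 base channels on 32×32 slices.

Masks are carried per tensor as "mask groups" (one binary matrix per
channel group), so a concatenation of decoder and skip features keeps
each group's own validity; the window normaliser sums `Σ(M)` over all
input channels.

## The critic and the adversarial objective

The critic scores 64×64 patches (configurable; 32×32 at desk scale)
centred on one randomly chosen lesion component, multiplied by the lesion
indicator so only the lesion region is judged (exposed as
`mask_input`). It has exactly four convolutional layers: three with
kernel 4, stride 2, padding 1 (64→32→16→8, LeakyReLU 0.2) and a final
layer collapsing the remaining field to one scalar — no sigmoid, since
the Wasserstein objective needs an unbounded score. Spectral
normalisation (one persistent power-iteration vector per layer,
initialised with 30 settling iterations) divides each kernel matrix by
its leading singular value; it is applied to the three non-output layers
by default (`sn_layers`).

Training maximises `E[D(real)] − E[D(fake)] − λ_gp·Gp` for the critic and
minimises `−E[D(fake)]` (plus the reconstruction, perceptual and texture
terms) for the generator, with `Gp = E[(‖∇_u D(u)‖₂ − 1)²]` at per-sample
uniform interpolates. `λ_gp = 10`, the usual WGAN-GP setting, is exposed
in `loss_weights()`. Because the critic is piecewise linear, the gradient
of `Gp` with respect to the weights is computed exactly (almost
everywhere) by a hand-derived double-backward pass: the scalar
`s = ⟨∇_u D, v⟩` equals a forward pass of `v` through the linearised
network, in which every weight appears exactly once, so its weight
gradients follow from one ordinary backward pass over that chain. The
only approximation is the standard one of treating the spectral-norm
power-iteration vectors as constants. Both networks are updated from the
same forward pass ("simultaneous" updates) with a configurable
critic-steps-per-generator-step ratio defaulting to 1.

## Losses

* **Reconstruction** (weights `w1 = 1` healthy, `w2 = 5` lesion):
  `w1‖M⊙(x−x̂)‖₁ + w2‖(1−M)⊙(x−x̂)‖₁`, mean-reduced over pixels by
  default with a sum-reduced option (worked examples in the tests state
  their reduction).
* **Perceptual**: `Σ_i (1/N_i)(‖Φ_i(x̂)−Φ_i(x)‖₁ + ‖Φ_i(z)−Φ_i(x)‖₁)`
  over the selected extractor layers, where `z = M⊙x + (1−M)⊙x̂` is the
  composite and `N_i` the element count of layer i's feature map.
* **Texture**: the same structure on Gram matrices
  `G = F F' / (C·H·W)`, position-invariant by construction.
* **Total**: `L_GAN + 1·L_rec + 0.05·L_perc + 100·L_tex`.

The feature extractor is pluggable. The package ships an identity
extractor and a frozen random-convolution extractor (fixed-seed
He-initialised 3×3 kernels with ReLU, grouped low/mid/high); random
convolutional features are a recognised basis for perceptual distances
and require no external weight file. Any object implementing the same
forward/backward interface — including a converted pretrained VGG-style
network, whose layer indices over the convolutional layers map onto the
low (1–5), mid (6–10), high (11+) grouping — can be substituted via
`synthesis_config(extractor = ...)`.

## Optimisation

AMSGrad (`beta1 = 0.5`, `beta2 = 0.999`, no bias correction, running
maximum of the second moment) with learning rates 1e-4 (generator) and
1e-5 (critic); batch size 6; He/Kaiming initialisation
(`sd = sqrt(2/fan_in)`, zero biases). The full-scale protocol is 800
epochs; the desk default is deliberately small and `steps` overrides
epochs for step-budgeted runs. Training aborts with a diagnostic naming
the offending component if any loss turns non-finite, and the whole loop
is bit-deterministic given the root seed (every random draw — batch
selection, patch choice, GP interpolates — flows through named
substreams).

At inference, `synthesize_lesions()` composites by default: pixels
outside the new lesion are bit-identical to the input, which guarantees
the mask is an exact label for the synthetic lesion. The raw generator
output is available with `composite_output = FALSE`.

## Realism evaluation

GLCM parameters follow common radiomics practice and are configurable:
32 gray levels (16 in the desk-scale studies) quantised over the ROI
range, distance 1, four angles (0°, 45°, 90°, 135°) averaged, symmetric
counting, ROI = the exact lesion mask. Energy is `Σ P²`; correlation is
the normalised covariance of the paired levels with the convention that a
constant ROI (zero marginal variance) scores 1. Feature histograms use 50
bins (20 at desk scale) over the pooled real ∪ synthetic range, and
`KL(real ‖ synthetic)` is computed with additive ε = 1e-8 smoothing and
renormalisation (the divergence direction is a flag; real-given-synthetic
is the default). The phantom generator's `lesion_noise_sigma` parameter
defines alternative texture families, which the report must — and, in the
tests, does — score as farther from real than same-family controls.

## Segmentation stage

The segmentation network is a compact U-Net: per stage one 3×3
convolution (batch norm, ReLU) and a stride-2 kernel-4 downsampling
convolution, a bottleneck at twice the deepest width, decoder stages of
2× nearest-neighbour upsampling + skip concatenation + 3×3 convolution,
and a sigmoid 1-channel head. The loss is
`0.5·L_CE + 1·L_Dice` with `L_Dice = 1 − (2Σyŷ+1)/(Σy+Σŷ+1)`; the +1
smoothing keeps the term defined (and zero) when prediction and label are
both empty, and the Dice term deliberately uses the raw probabilities so
that identity holds exactly. Training uses AMSGrad at learning rate
3e-4, batch 16; the full protocol is 150 epochs and 5 folds.

Cross-validation folds partition the *subjects* of the real set; the
synthetic set joins every training fold and can never enter an evaluation
fold (structurally, and asserted). Metrics — DSC, vPSC, vSEN in percent —
are computed per held-out subject volume (stacking the subject's slices)
with a 0.5 binarisation threshold; per-slice evaluation and fold-level
summaries are also reported. Degenerate conventions: both volumes empty →
100 everywhere; exactly one empty → 0. DSC equals the harmonic mean of
vPSC and vSEN whenever the overlap is nonempty — an algebraic identity
the tests verify to 1e-9.

## Problem sizes in the bundled studies

The package's own studies (test suite and `scripts/acceptance.R`) run at
a desk-scale profile chosen once: 32×32 phantoms, a 4-stage × 8-channel
generator, a 32×32-patch critic, 200–300 adversarial steps, 100 synthetic
slices on lesion-free substrate, and a depth-3 × 4-channel U-Net trained
20 epochs under 2-fold subject-level cross-validation on 200 real slices,
replicated over five seeds. These sizes keep a complete CPU run in
minutes while leaving the augmentation effect measurable; the full-scale
protocol values remain the package defaults where a published value
exists.

## Known limitations

* 2-D only; no volumetric synthesis or 3-D partial convolution.
* The convolution engine is CPU-only and sized for method studies, not
  for 512×512 clinical volumes at 800 epochs.
* The spectral-norm gradient treats the power-iteration vectors as
  constants (the standard approximation); near initialisation the
  estimated singular value is accurate to a few percent.
* Phantom realism bounds what the bundled experiments can show: they
  demonstrate algorithmic correctness and the direction of the
  augmentation benefit, not clinical-scale effect sizes.
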