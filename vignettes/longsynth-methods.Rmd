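---
title: "Methods: adversarial-perceptual longitudinal MR image prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adversarial-perceptual longitudinal MR image prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Longitudinal infant neuroimaging studies acquire MR scans at fixed ages
(here 6 and 12 months), but attrition and scan failure leave many subjects
with only one of the two timepoints.  Dropping incomplete subjects shrinks
and potentially biases the sample; imputing the missing *image* lets every
subject contribute to downstream analyses that need complete longitudinal
pairs.  The task is hard because the infant brain changes dramatically
between 6 and 12 months: it grows, and myelination reshapes the tissue
contrast — the white/gray-matter intensity relationship in T1w images
strengthens over the first year while the T2w relationship weakens and
partially inverts.  A missing-timepoint predictor therefore has to move
both geometry and contrast, not merely copy appearance.

`longsynth` implements a 3D image-to-image translation approach to this
problem: a U-Net generator maps the normalized image at the observed age
to the image at the missing age, trained with a composite objective, and a
multi-contrast variant predicts T1w and T2w jointly.

# Model and objectives

Let $x$ be the input-age image and $y$ the target-age image, both
intensity-normalized to $(-1, 1)$.  The generator $G$ and discriminator
$D$ play the least-squares adversarial game

$$\mathcal{L}_{adv}(G, D) =
  \mathbb{E}_x\big[(1 - D(G(x)))^2\big] + \mathbb{E}_y\big[D(y)^2\big],$$

with $D$ ascending and $G$ descending.  Adversarial realism alone does not
force the output to match *this* subject's target, so two consistency
terms are added: the voxel-wise reconstruction loss
$\mathcal{L}_{vr} = \mathbb{E}\,\lVert y - G(x)\rVert_1$ and the
perceptual loss
$\mathcal{L}_p = \mathbb{E}\,\lVert \phi_m(y) - \phi_m(G(x))\rVert_1$,
where $\phi_m$ is the $m$-th block of a frozen encoder-style feature
extractor.  The L1 term preserves global structure but over-smooths; the
feature-space term restores sharpness.  The total generator objective is

$$\mathcal{L} = \mathcal{L}_{adv} + \alpha\,\mathcal{L}_{vr} +
  \beta\,\mathcal{L}_p, \qquad \alpha = \beta = 25,\; m = 1 .$$

In the multi-contrast configuration (`variant = "mpgan"`) the T1w and T2w
input images are concatenated channel-wise and fed to a **shared encoder**;
two **independent decoders** (each with its own skip connections into the
shared encoder features) emit the predicted T1w and T2w images, scored by
two separate discriminators.  The adversarial, reconstruction, and
perceptual terms are summed over the two contrasts.  The shared encoder is
what lets complementary contrast information (strong T2w tissue contrast
at 6 months, strong T1w contrast at 12 months) support both predictions.

## Conventions behind the numbers

Three conventions matter for reproducing loss values:

* **Expectations are means.**  The batch size is 1, and all L1 norms and
  discriminator score maps are *averaged* over voxels / feature elements /
  map positions rather than summed.  This makes $\alpha$ and $\beta$
  resolution-independent; the values 25 are tied to this choice.
* **Descent-form adversarial losses.**  The printed minmax objective has
  $D$ ascending on $(1-D(G(x)))^2 + D(y)^2$.  The implementation descends
  on the equivalent $\mathcal{L}_D = (1-D(y))^2 + D(G(x))^2$, which shares
  the optima ($D(\text{real})\to 1$, $D(\text{fake})\to 0$ for a
  sigmoid-bounded $D$); `adversarial_terms(literal_ascent = TRUE)` exposes
  the literal form.
* **Single perceptual layer.** $m = 1$ by default; multi-layer sums are
  deliberately out of scope.

# Architectures

The generator is a 3D U-Net: an encoder of four stages of two 3×3×3
convolutions (20, 40 / 40, 80 / 80, 160 / 160, 320 channels), each of the
first three stages followed by 2×2×2 max-pooling; a decoder mirroring it
with 160, 160 / 80, 80 / 40, 40 channels, nearest-neighbour 2× upsampling,
and skip connections from the pre-pool encoder features; and a final 1×1×1
convolution with tanh.  Every convolution except the last is followed by
instance normalization and ReLU.  The discriminator is a patch design:
four 4×4×4 stride-2 convolutions (64, 128, 256, 512 channels, LeakyReLU
slope 0.2, instance normalization except on the first), then a stride-1
convolution to one channel and a sigmoid, so a 32³ input yields a 2³ score
map.  The feature extractor is an encoder of four double-convolution
blocks ((32, 64), (64, 128), (128, 256), (256, 512)) with pooling after
the first three; $\phi_1$ of a 32³ volume is a 64-channel 16³ grid.

Choices the architecture tables leave open, fixed here:

* **Same-padding everywhere** so the U-Net maps a grid to a grid of equal
  shape (input axes must be divisible by 8 for the three exact 2×
  downsamplings).  The stride-1 4×4×4 discriminator head uses asymmetric
  (1, 2) padding to preserve its grid.
* **Upsampling** is nearest-neighbour followed by the listed 3×3×3
  convolution, avoiding the checkerboard artifacts of transposed
  convolutions.
* **Instance normalization without learned affine parameters**, suited to
  batch size 1.  Two consequences are documented rather than hidden:
  (i) with a single spatial voxel the statistics are degenerate — the
  output would be identically zero and would sever gradient flow — so the
  operation falls back to the identity there (this matters for 16³
  discriminator inputs, which reach 1³ after four stride-2 layers);
  (ii) normalization statistics are global over the volume, so strict
  translation equivariance of the generator does not hold; the
  convolutional path itself is verified shift-equivariant (to ~1e-7) with
  `generator_spec(norm = FALSE)`.
* **Initialization** is zero-mean Gaussian with sd 0.02 (the standard for
  this GAN family), seed-controlled; biases start at zero.
* **Feature-extractor weights.**  The reference pipeline uses a
  self-supervised pretrained 3D encoder.  This package implements the
  architecture and can load external weights
  (`feature_extractor_spec(weights_source = "external-file")` +
  `load_weights()`), but defaults to a fixed-seed random frozen encoder so
  that everything runs without downloads — random frozen encoders are an
  accepted, documented practice for perceptual losses.  $\phi_m$ is the
  block-$m$ output *after* its pooling step.
* **Unconditional discriminator**: the objective is written as
  $D(G(x))$ and $D(y)$ without conditioning on $x$, and that is what is
  built.

# Training protocol

Adam with $\beta_1 = 0.5$, $\beta_2 = 0.999$ (the GAN convention; the
moments are not stated in the protocol this reproduces), batch size 1,
one discriminator update followed by one generator update per iteration,
with both discriminators updated jointly in the multi-contrast setting.
The learning rate is $2\times 10^{-4}$ for the first 44 epochs, then
halved every 22 epochs for an additional 176 epochs — 220 epochs total
with exactly 8 decays, reaching $2\times 10^{-4} \cdot 0.5^8$.
`learning_rate()` implements the schedule exactly (first decay at 0-based
epoch 44) and `fit_model()` records it per epoch.  Model selection is by
minimum validation voxel-wise reconstruction loss, falling back to the
final epoch when no validation split exists.  The six ablation variants —
`unet_lvr`, `unet_lvr_lp`, `gan`, `gan_lvr`, `pgan`, `mpgan` — differ only
in which loss terms are active, so e.g. `pgan` with $\beta = 0$ reproduces
`gan_lvr` exactly (regression-tested).

Both prediction directions (6→12 and 12→6 months) are separate models with
their own configurations; `impute_cohort()` routes each incomplete subject
to the direction its missing timepoint requires.

**Imputation contract.**  Imputed volumes never overwrite real data, are
flagged in the manifests, and may serve as additional *training* examples
only: a subject holding imputed data cannot be assigned to the validation
or test split (`assign_split()` refuses, and `impute_cohort()` errors if
an incomplete subject is found parked in val/test).

# The synthetic phantom cohort

The real cohort behind this method is controlled-access, so the package
ships a deterministic phantom simulator that reproduces the *structure* of
the data regime rather than its anatomy: per subject, two contrasts at two
ages, voxel-aligned ground-truth labels, growth between ages, and a
myelination-like contrast change.

Geometry is a set of nested ellipsoids — a CSF shell enclosing a cortical
gray-matter shell enclosing a white-matter core — plus a central deep-GM
ellipsoid and six bilateral (mirrored) subcortical blobs (thalamus,
caudate, putamen, pallidum, hippocampus, amygdala) inside the WM core, so
that both a "tissue" and a "subcortical" evaluation exist.  The 12-month
geometry is the 6-month geometry scaled about the volume centre by
`growth_factor` (default 1.07, i.e. ≈ +23 % brain volume over the
half-year, a realistic first-year increment).  Intensities are per-tissue,
per-contrast, per-age means plus Gaussian noise (sd 2 on a 0–100 intensity
scale), Gaussian-smoothed (FWHM 1 mm) as a partial-volume stand-in, then
min–max normalized to $[-1, 1]$ with the exact-zero background excluded
from the min/max and mapped to $-1$ (the skull-stripped exterior would
otherwise compress the brain contrast; per-volume rather than cohort-wide
normalization is the package's documented choice).  The default intensity
table makes the WM/cortical-GM gap small at 6 months and large at 12
months in the T1-like contrast and inverts this in the T2-like contrast,
and keeps all tissue means pairwise distinct per contrast and age so that
nearest-mean tissue classification (`segment_by_intensity()`, the
package's synthetic stand-in for an automatic segmentation algorithm) is
well defined.

What the phantom does *not* emulate: cortical folding, anatomical shape
variability beyond a global radius jitter (±3 %), lesions, scanner
artifacts, bias fields, or registration error.  Passing tests on the
phantom therefore demonstrate that the optimization, architectures,
metrics, and workflow are correct — not that the method reaches any
particular accuracy on real infant MRI.

# Evaluation metrics

Segmentation agreement between two binary masks $S_1$ (reference) and
$S_2$ is quantified by: relative absolute volume difference
$\mathrm{AVD} = |V_{S_1} - V_{S_2}| / V_{S_1} \times 100\%$ (asymmetric);
average symmetric surface distance, the border-size-weighted mean of
nearest-border distances in both directions (mm); Dice
$2|S_1 \cap S_2| / (|S_1| + |S_2|)$; and the Tanimoto error
$(|S_1 \cup S_2| - |S_1 \cap S_2|)/|S_1 \cup S_2| \times 100\%$.  The
fused score averages AVD, ASD, and Tanimoto error after scaling each by
its inter-expert reference value (5.6 %, 0.27 mm, 15.8 %):
$\mathrm{FS} = \tfrac13(\mathrm{AVD}/5.6 + \mathrm{ASD}/0.27 +
\mathrm{TE}/15.8)$, oriented so that *lower is better* and 1.0 means
"agreement at the level of human experts" — the orientation consistent
with ranking better methods lower.

Numerical choices: a **border voxel** is a foreground voxel with at least
one 6-connected face neighbour that is background, with out-of-grid
counting as background; distances are Euclidean between voxel centres in
mm using the stored spacing; ASD is computed with an exact separable
Euclidean distance transform of the border sets, validated against an
$O(n^2)$ all-pairs oracle to 1e-9; structures empty in either map are
reported as explicit *undefined* rows, never silently dropped or coerced
to 0.

# Desk-scale study conditions

All tests and the acceptance script run on one CPU with no downloads, so
problem sizes are scaled down while every contract stays full-size:

* Phantom grids of 32³ (training/convergence checks, growth checks) and
  16³ (workflow checks) at 1 mm spacing; cohorts of 3–10 subjects.
* Narrow-width networks for training runs (encoder 4–64, decoder 32–8,
  discriminator 8–64, extractor 4–64 channels); the full Table-width
  builders (20–320 etc., 6.4 M generator parameters) are exercised in
  forward-shape contracts.
* The 25-epoch smoke training uses a constant Adam learning rate of
  5e-2 instead of 2e-4: with 3 training subjects and batch size 1, 25
  epochs are only 75 gradient steps, and a tanh output cannot traverse an
  $O(1)$ intensity range at 2e-4.  This is a configuration choice of the
  desk-scale demonstration, not a change to the published schedule, which
  remains the default (`lr0 = 2e-4`, 220 epochs).

Determinism: every stage (phantom, initialization, shuffling) is seeded,
the pipeline derives per-stage seeds from one global seed by fixed
offsets, and re-running a fit with the same configuration reproduces the
training history bit-identically on the same machine.

# Known limitations

* No GPU path and no mixed precision; the native kernels are practical at
  desk scale only.
* Whole-volume training only (batch size 1); no patch sampling.
* The perceptual extractor defaults to random frozen weights; results
  with pretrained weights will differ.
* The phantom's simplifications listed above; in particular,
  intensity-based segmentation of the phantom is far easier than
  multi-atlas segmentation of real infant MRI.
* Cycle-consistency variants, Hausdorff distance, significance testing
  between method variants, and learned perceptual similarity scoring are
  out of scope.
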