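---
title: "Residual-learning super-resolution for MRI-like slices: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residual-learning super-resolution for MRI-like slices: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Stereotactic radiosurgery of the trigeminal nerve depends on MRI that
resolves a sub-millimetre structure, and on the guarantee that any image
processing applied before treatment planning does not move the target in
the frame coordinate system. `mrisr` implements a single-image
super-resolution (SISR) pipeline for single-channel medical slices built
around a 20-layer residual convolutional network (the VDSR architecture),
and an evaluation design that asks two questions:

1. does the learned reconstruction beat plain bicubic interpolation in
   PSNR/SSIM at scale factors 2, 3 and 4, under a paired test, and
2. does a point target embedded in the image stay where it was
   (sub-pixel) after reconstruction?

Because clinical MRI of this kind is not redistributable, the package
ships a synthetic phantom generator as a first-class, tested module; all
quantitative claims in the test suite and the acceptance script are made
on phantoms, and their scope is discussed at the end of this vignette.

## The model

Let $Y$ be a ground-truth luminance grid in $[0,1]$ and let
$X = U_s(D_s(Y))$ be its bicubic degradation: downscale by $1/s$ with
antialiasing, then bicubic upscale back to the original grid, for a scale
factor $s \in \{2,3,4\}$. Because $X$ and $Y$ share their low-frequency
content, the network $f$ is trained to predict the *residual*
$R = Y - X$ rather than $Y$ itself, and reconstruction is

$$\bar Y = \mathrm{clip}_{[0,1]}\!\left(X + f(X)\right).$$

$f$ is fully convolutional: layer 1 maps 1 channel to 64, layers 2–19 map
64 to 64, and layer 20 is a linear 3×3 convolution back to a single
channel so the residual can be added to the luminance grid. Every layer
is a 3×3 convolution zero-padded by 1 px (spatial dimensions are
preserved end-to-end, which is what lets a model trained on 41×41 patches
run unchanged on full 256×256 slices); every hidden layer is followed by
ReLU. With depth 20 and width 64 the model has 665,921 parameters.

The training loss is

$$L = \tfrac12\,\overline{(R - f(X))^2},$$

i.e. half the *mean* squared error over pixels and batch. The mean (as
opposed to sum) normalisation is a deliberate choice: it makes the loss
scale, and with it the learning rate and the gradient-clipping threshold,
independent of patch size and batch size, so the same recipe applies to
41×41 patches and full grids.

Only the luminance (Y) channel passes through the network. Slices are
converted to YCbCr; for grayscale MRI the chrominance channels are the
neutral constant 0.5 and recombination is the identity on them, but the
three-channel path is retained structurally (and exercised in tests with
the standard full-range JPEG transform).

## Training recipe

The optimizer is stochastic gradient descent with momentum, with the
following defaults (`trainConfig()`):

| parameter            | default | unit |
|----------------------|--------:|------|
| max epochs           | 100     | epochs |
| mini-batch size      | 64      | patches |
| momentum             | 0.9     | – |
| L2 regularization    | 1e-4    | – (weights only; biases undecayed) |
| gradient threshold   | 0.01    | L2 norm of the full gradient |
| initial learning rate| 0.1     | – |
| LR drop factor       | 0.1     | every 10 epochs |

The per-step order of operations is documented and tested: (1) add the
L2-decay term to the weight gradients, (2) clip the *global* gradient L2
norm at the threshold, (3) momentum update, (4) weight update. Clipping
the global norm (rather than per-layer norms) is the plainer reading of
"gradient threshold calculated using the L2 norm"; the choice is
observable in the recorded per-step post-clip norms, which the history
object exposes and the tests bound at `threshold + 1e-12`.

The learning-rate schedule is
`initialLR * dropFactor^floor((epoch-1)/period)`; the training history's
`lr` column is required (and tested) to match this closed form exactly.

### Initialization

Hidden layers are He-normal (`sd = sqrt(2/(9 * fan_in))`) under a seed.
The final reconstruction layer is **zero-initialized**. This is the one
place the package departs from uniform He initialization, and it is a
considered choice: with a He-initialized output layer the untrained
residual branch injects noise of magnitude comparable to the image
itself, and under a clipped-gradient recipe (step norm at most
`lr * threshold = 1e-3` before momentum) a short training run cannot even
climb back to bicubic parity. Zero-initializing the residual branch —
standard practice for residual architectures — makes the untrained model
*exactly* equal to bicubic restoration, so training starts at the
baseline and can only improve on it. The equality is exact and is
asserted bit-for-bit in the tests.

### Desk-scale profile

`deskTrainConfig()` is the package's small-corpus profile, used by the
acceptance tests and script: 5 epochs over ~216 patches (six 256×256
phantoms, non-overlapping 41×41 patches at scale 2, a 10% validation
split) at mini-batch 8. Three settings are compressed to desk scale,
for stated reasons:

- **batch 8** rather than 64: at ~200 patches a batch of 64 permits
  only ~3 optimizer steps per epoch, too few for any recipe to show
  learning;
- **initial learning rate 0.01, dropped ×0.1 every 2 epochs** rather
  than 0.1 every 10: the schedule's annealing structure is kept but
  compressed to the 5-epoch horizon. At full scale the 0.1 rate is
  tamed by hundreds of thousands of clipped steps; over a few dozen
  steps, 0.1 with momentum 0.9 places the effective step at the
  stability edge of the optimization, so the run orbits the optimum and
  whether the final weights beat the initial ones becomes a coin flip
  of the shuffle seed (observed across seed sets during design);
- **best-validation weight selection** (`returnBest`, a standard config
  flag): the returned model is the best point actually visited, which
  protects a short run against ending mid-oscillation.

Momentum, L2 decay, gradient clipping and the drop factor are the
standard recipe unchanged. At this scale training takes a few minutes on
one CPU and produces a small but systematic PSNR gain over bicubic — the
paired test across 16 held-out phantoms is what turns "small but
systematic" into a significant comparison.

## Bicubic resampling

Degradation, upscaling, resizing and augmentation all use one separable
bicubic resampler (Keys kernel, $a=-0.5$). When downscaling, the kernel
support is widened by the scale factor (antialiasing); windows are
clipped at the image border and the surviving weights renormalized. This
is the convolution-resampling convention shared by the major imaging
toolchains, and the implementation is pinned by frozen reference-resampler
outputs in the test suite (agreement to ~1e-7, tested at 1e-3). For
non-divisible sizes the downscale target is `ceiling(n/scale)`, so a
256×256 grid at scale 3 degrades through 86×86 and returns at exactly
256×256.

Degraded grids are clipped to $[0,1]$ (bicubic overshoot would otherwise
leave the valid range; storage as an 8-bit image would clip anyway).
Inside the training-pair path everything stays real-valued double
precision: quantization to 8 bits happens only at file write.

The stored residual satisfies `r == yTrue - x` bit-exactly (it is
defined as that difference and validity-checked with `identical()`);
note that the reconstruction `x + r` recovers `yTrue` only to 1 ulp,
which is the nature of floating-point subtraction, and the tests assert
it at `1e-15`.

## Augmentation

One affine draw per replicate: integer translations `tx`, `ty` uniform
on [−30, 30] px and an isotropic zoom uniform on [0.9, 1.1], applied with
bicubic interpolation, zero fill outside the source, output size
preserved. The translation range is read as integer pixels (a draw of
integers), the zoom as continuous. The ground-truth slice is augmented
*first* and then degraded, which keeps every (X, R) pair internally
consistent. `applyAffine()` exposes the deterministic core so a forced
identity draw (exactly the identity map, tested) and exact delta-image
translations can be verified independently of the RNG.

## The phantom generator

`generatePhantom()` renders, in order:

1. **Nested elliptical tissue regions** (background, scalp, white matter,
   deep grey, CSF) at exact preset levels — boundaries are hard, so a
   noiseless phantom is piecewise constant and its unique values *equal*
   the preset levels, a property the tests use. Five per-sequence presets
   (T2, T1, CE-T1, VISTA, PD analogs) give plausible contrasts (bright
   CSF on T2/VISTA, dark on T1); they are invented contrasts, not a
   physical signal model.
2. **A thin curvilinear filament** (trigeminal-nerve analog): an
   anti-aliased polyline ~1.8 px wide, dark against bright CSF on
   T2-like sequences and bright on T1-like ones. It is the structure
   bicubic degradation visibly destroys, which is what gives the
   super-resolution network something clinically shaped to restore.
3. **Optional Gaussian fiducial targets** at real-valued sub-pixel
   coordinates, used by the coordinate-invariance check.
4. **Rician noise**: $|signal + n_1 + i n_2|$ with independent Gaussian
   components of scale σ (default 0.015) — the magnitude-image noise law
   of MRI. The implied CDF (via the noncentral-χ² identity) is exposed as
   `riceCDF()` and the tests verify the generator against it with
   Kolmogorov–Smirnov at α = 0.01 over ten seeds.

Everything is a pure function of the spec (seed included):
`generateCohort()` derives per-slice seeds deterministically from a
cohort seed and jitters geometry, filament control points and fiducial
positions within small ranges so cohorts are internally varied yet
bit-reproducible.

What the phantoms deliberately do **not** model: coil inhomogeneity,
partial-volume gradients at tissue boundaries, motion/ghosting
artifacts, anatomical variability beyond affine-ish jitter, k-space
acquisition effects. Consequences for interpretation are discussed
below.

## Metrics

MSE, PSNR (`10·log10(peak²/MSE)`, with identical images reported as an
infinite-PSNR *flag*, never an error) and SSIM with the constants
$C_1=(0.01L)^2$, $C_2=(0.03L)^2$, $C_3=C_2/2$. SSIM comes in two modes:

- **windowed** (default): the luminance/contrast/structure triple per
  11×11 Gaussian window (σ = 1.5) over the valid interior, SSIM map
  averaged — the field-standard convention, pinned against frozen
  reference-implementation values at 1e-4;
- **global**: one triple from whole-image moments — the
  equation-literal reading, kept for the closed-form tests.

Moments use the population convention (divide by *n*). The σAσB product
is computed as `sqrt(vA*vB)`, which makes `ssim(A, A) == 1` *exactly*
(IEEE `sqrt(x*x)` rounds back to `x`); with the naive `sA*sB` product the
identity holds only to 1 ulp. `peak`/`dynamicRange` default to 1 for the
package's [0,1] grids; PSNR is identical either way and the SSIM
constants are scale-invariant in L.

## Evaluation design

`evaluatePairs()` follows the degrade-then-restore protocol: for each
ground-truth slice and scale, the degraded grid itself is the bicubic
restoration, and the network's reconstruction of that grid is the SR
restoration; both are scored against the ground truth, giving paired
records. Image/scale pairs with SSIM = 1 (within 1e-12) for either
method are excluded pairwise — a lossless degradation (e.g. a constant
slice) carries no information about restoration quality. Per-scale means
and a paired t-test (internally implemented; two-sided, n−1 df;
cross-checked against the standard library routine at 1e-10) make up the
summary table. Raw p-values are reported without multiple-testing
adjustment across the six scale×metric cells, matching the design this
table mirrors; the table's documentation says so.

A scale-2-trained desk model is evaluated at scales 2, 3 and 4 in the
acceptance script; only the scale-2 direction is asserted by the tests,
since transferring a scale-2 residual model to harsher degradations is
not part of the desk-scale claim.

### Coordinate invariance

`localizeTarget()` finds, within a search window centred on the nominal
coordinate, the connected region above half the local maximum and takes
the centroid weighted by *intensity above that threshold*. Weighting
above-threshold (rather than raw intensity) makes the weights vanish
continuously at the region boundary and removes the background-offset
bias; with a grid-aligned symmetric peak the estimate is exact to
numerical precision, and for arbitrary sub-pixel centres the hard
half-max truncation limits accuracy to ~0.01 px — two orders below the
0.5 px tolerance. The tolerance itself (0.5 px, i.e. "sub-pixel means no
difference at image resolution") is the package's stand-in for a
qualitative no-difference claim; it is configurable, converted to mm when
pixel spacing is known, and the check fails loudly when no above-threshold
region exists.

One geometric pre-condition matters in practice: the search window must
lie within a single tissue class. If a neighboring structure inside the
window is brighter than half the fiducial peak, the half-max region can
flood into it and drag the centroid by several pixels — a
localization-window artifact, not a reconstruction displacement. The
default fiducial placement in the phantom experiments (x = 185, y = 96
on the 256 grid) keeps the window wholly inside white matter under all
cohort jitters.

## Numerical and I/O choices

- **8-bit quantization** is `floor(p*255 + 0.5)/255` — round-half-up,
  documented because R's `round()` is round-half-even; 0.5 maps to level
  128. Idempotent, tested.
- **DICOM** reading supports uncompressed little-endian single-frame
  files (explicit and implicit VR); RescaleSlope/Intercept are applied
  before normalisation. No single display window suits every series, so
  the default maps each slice's own min–max to [0,1] and a fixed
  `window = c(lo, hi)` option applies one linear map across a series. Compressed transfer syntaxes are rejected with an explicit
  unsupported-format error.
- **PNG** (lossless at 8 bits; round-trips bit-exactly) is the default
  working format; **JPEG** is supported with an explicit quality
  parameter (default 95).
- **Checkpoints** store depth/width/seed/provenance plus an MD5 of the
  serialized weights, verified on load, so a corrupt or hand-edited
  checkpoint cannot silently feed inference.
- **Determinism**: every stochastic operation takes a seed and restores
  the caller's RNG state; derived seeds stay below 2^31. Cohort, training
  set manifest, checkpoint hash and evaluation table are bit-identical
  across reruns with equal seeds, which the test suite asserts.

## Problem sizes used by tests and the acceptance script

Training: 216 patches of 41×41 at scale 2 from six 256×256 phantoms,
5 epochs, batch 8 (≈135 optimizer steps). Evaluation: 16 held-out
256×256 phantoms (scales 2/3/4 in the script, scale 2 in the tests).
Coordinate check: 20 fiducial phantoms at scale 2. Schedule and update
oracles run on deliberately tiny networks (depth 2–4, width 1–8). These
sizes are the package's desk-scale study conditions; the same code runs
unchanged on larger corpora by swapping the config.

## What passing tests do and do not show

The phantom experiments demonstrate that the pipeline's mechanics are
correct (residual algebra, schedule, update rule, metric agreement with
references, determinism) and that the *direction* of the headline
comparison — super-resolution above bicubic in PSNR with paired
significance, targets unmoved to sub-pixel tolerance — is reproduced
under controlled conditions. They do not certify clinical image quality:
phantoms lack the noise structure, anatomy and artifact spectrum of
patient MRI, the desk-scale gain over bicubic is far smaller than what a
full training corpus and 100-epoch schedule can deliver, and absolute
PSNR/SSIM levels on phantoms are not comparable to values measured on
clinical data.

## Known limitations

- Only the bicubic degradation model is implemented; learned or
  physics-based degradations (blur kernels, k-space truncation) are out
  of scope.
- The network is the single-channel 2-D VDSR architecture; no 3-D
  convolution, attention or alternative SR families.
- DICOM support is single-frame and uncompressed; no multi-frame or
  PACS networking.
- The paired t-test assumes approximately normal per-image differences;
  with 16 images the test is adequate for the smooth phantom
  distributions but is not a substitute for the full-corpus analysis.
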