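# mrisr — residual-learning super-resolution for MRI-like images

`mrisr` is an R package for single-image super-resolution (SISR) of
single-channel medical image slices, built for the setting where image
enhancement must not displace a stereotactic target: MRI of the
trigeminal nerve ahead of radiosurgical planning. It implements the full
pipeline — synthetic MRI phantoms, slice I/O, residual training-pair
construction, a 20-layer residual convolutional network (VDSR
architecture) trained from scratch, reconstruction, and a paired
evaluation design — with every stage under test.

## The model

Given a ground-truth luminance grid $Y$ and its bicubic degradation
$X$ (downscale by $1/s$ with antialiasing, bicubic upscale back; scale
factor $s \in \{2,3,4\}$), the network $f$ learns the residual
$R = Y - X$ by minimising

$$L = \tfrac12\,\overline{(R - f(X))^2},$$

and reconstructs $\bar Y = \mathrm{clip}(X + f(X), 0, 1)$. The network
is fully convolutional — twenty zero-padded 3×3 convolution layers (64
filters, ReLU; linear single-channel reconstruction layer; 665,921
parameters) — so it trains on 41×41 patches and runs on full 256×256
slices unchanged. Training is SGDM: momentum 0.9, L2 regularization
1e-4, per-batch global gradient L2-norm clipping at 0.01, learning rate
0.1 dropped ×0.1 every 10 epochs, mini-batch 64, up to 100 epochs.
Super-resolution is applied to the luminance (Y) channel of the YCbCr
decomposition only.

Quality is scored by PSNR and SSIM (windowed 11×11 Gaussian σ = 1.5 by
default; an equation-literal global mode is also provided), compared
bicubic-vs-SR with a paired t-test per scale factor, and geometric
fidelity is checked by localizing Gaussian fiducial targets to sub-pixel
precision in ground truth and reconstruction.

Patient MRI of this kind is not redistributable, so the package ships a
tested phantom generator: 256×256 slices with nested elliptical tissue
regions under five sequence-contrast presets (T2/T1/CE-T1/VISTA/PD
analogs), a thin high-contrast filament standing in for the trigeminal
nerve, optional fiducial bumps, and Rician noise.

## Worked example

Train a desk-scale model on phantom patches and compare it with bicubic
interpolation on held-out phantoms:

```r
library(mrisr)

base <- phantomSpec(seed = 1, size = 256, sequence = "T2", noiseSigma = 0.015)
cohort <- generateCohort(6, base, seed = 101)
ts <- buildTrainingSet(cohort$slices, scales = 2L, seed = 202)
nPairs(ts)
#> [1] 216

fit <- trainVDSR(ts, deskTrainConfig(shuffleSeed = 404),
                 initVDSR(20, 64, seed = 303))

heldout <- generateCohort(16, base, seed = 505)
rec <- evaluatePairs(heldout$slices, fit$model, scales = 2L)
summarizeEval(excludePerfect(rec))
#>   scale n_images psnr_bicubic  psnr_sr ssim_bicubic   ssim_sr   t_psnr
#> 1     2       16     32.78786 32.79028    0.8674702 0.8674873 104.6162
#>        p_psnr   t_ssim       p_ssim
#> 1 6.74784e-23 66.68105 5.714592e-20
```

Reading the table: across 16 held-out phantoms at scale factor 2, the
super-resolved reconstructions average 32.790 dB PSNR against 32.788 dB
for plain bicubic, with SSIM 0.86749 vs 0.86747. The gain is small —
five epochs over ~200 patches under a clipped-gradient recipe move the
weights very little — but it is *systematic*: the paired t statistic of
104.6 (p ≈ 7e-23) says SR improved essentially every phantom by the
same small margin. The same trained model leaves embedded fiducial
targets in place:

```r
fidSpec <- phantomSpec(seed = 1, size = 256, sequence = "T2", noiseSigma = 0.015,
                       fiducial = list(x = 185, y = 96, amplitude = 0.55, sigma = 1.6))
fids <- generateCohort(20, fidSpec, seed = 606)
s <- fids$slices[[1]]
sr <- superResolve(fit$model, MRISlice(degradeSlice(s, 2)), 2)
coordinateCheck(s, sr@image,
                targetCoordinate(fids$manifest$fid_x[1], fids$manifest$fid_y[1]))
#>     true_x   true_y     gt_x     gt_y     sr_x     sr_y   shift_px shift_mm pass
#> 1 184.2449 95.52833 184.2786 95.52242 184.2584 95.50288 0.02814336       NA TRUE
```

`shift_px` is the Euclidean distance between the target localized in the
ground truth and in the reconstruction — here ~0.03 px, far below the
0.5 px "no difference at image resolution" tolerance.

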