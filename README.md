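# ivmproc

Processing toolbox for serial intravital 2-photon microscopy stacks, aimed at
biomedical imaging groups who record multichannel kidney (or other abdominal
organ) volumes in vivo and need the standard post-acquisition chain:
denoising, drift correction, serial-session alignment, and quantitative
validation — scriptable and reproducible rather than click-driven.

Everything operates on a `stack5d`: a calibrated `(t, z, c, y, x)` intensity
array (voxel size in µm, frame interval in s) read from and written to
multi-page TIFF with a JSON calibration sidecar.

## What it does

**Variance-stabilized denoising** (`denoise_vst()`). Detector noise is mixed
Poisson-Gaussian: `z = α·p + n`, `p ~ Poisson(y)`, `n ~ N(µ, σ²)`, so the
variance `α²y + σ²` grows with the signal. The pipeline estimates σ (robust
Laplacian-MAD, pooled over a ≤10-slice mosaic for volumes), applies the
generalized Anscombe transform

&nbsp;&nbsp;&nbsp;&nbsp;f(z) = (2/α) √(αz + 3α²/8 + σ² − αµ)

to make the noise unit-variance Gaussian, rescales to [0, 1], runs a
two-stage collaborative patch filter (block matching, DCT + Walsh–Hadamard
group transform, hard thresholding at 2.7σ, then Wiener refinement; 8×8
patches slice-wise or 4×4×4 cubes volumetrically in overlapping 10-frame
chunks), and inverts the transform with the closed-form exact-unbiased
inverse before re-quantizing. A Median-3D baseline (5×5×5) is included.

**Drift correction** (`register_2d()`). All channels are summed into a
contrast-stretched registration channel; per-frame translations are estimated
from multi-scale difference-of-Gaussian keypoints with ratio-test matching, a
consensus translation fit and sub-pixel NCC refinement; the corrections are
applied to every channel by bilinear interpolation and the registration
channel is discarded. Works along `t` (time series) or `z` (breathing
artefacts in volumes).

**Serial 3D registration** (`register_serial()`). Rigid (rotation +
translation only — deliberately, so genuine tissue remodeling is not
absorbed by the warp) least-squares fit of user-placed landmark pairs
(BigWarp-compatible CSV, µm) by the SVD/Kabsch procedure, then trilinear
resampling of the moving volume onto the reference grid.

**Ground truth & benchmarking** (`align_replicates_translation()`,
`generate_ground_truth()`, `benchmark_denoisers()`). Replicates of one volume
are aligned by FFT normalized cross-correlation, averaged into a low-noise
ground truth, and any set of denoisers is scored per slice with PSNR / RMSE /
MAE (n = time points × slices per channel).

**Synthetic phantom** (`phantom_spec()`, `make_phantom()`, `corrupt()`,
`make_validation_replicates()`, `make_serial_pair()`, `inject_drift()`).
A deterministic renal phantom — endothelial filament network, hollow tubules
with lysosome-like puncta, capsular fibrils, on a smooth autofluorescence
bed — with exact ground truth for every stage (noise parameters, drift
trajectories, rigid transforms, landmark correspondences), so the entire
toolbox is testable end to end without any external data.

## Worked example

Simulate the replicate validation experiment at desk scale, build the
averaged ground truth, and benchmark three denoisers:

```r
library(ivmproc)

spec <- phantom_spec(extents = c(t = 1, z = 45, c = 3, y = 64, x = 64),
                     n_filaments = 6, n_tubes = 2, n_puncta = 5,
                     n_fibrils = 10, seed = 1)
val <- make_validation_replicates(spec, n = 25,
                                  model = pg_model(alpha = 4, sigma = 10),
                                  seed = 1)
aligned <- align_replicates_translation(val$replicates)
gt <- generate_ground_truth(aligned$aligned)

report <- benchmark_denoisers(
  val$replicates[1:2], gt,
  list(median3d = function(s) denoise_vst(s, method = "median3d"),
       vst2d    = function(s) denoise_vst(s, method = "vst2d"),
       vst3d    = function(s) denoise_vst(s, method = "vst3d")))
print(report)
```

```
<metrics_report>
# A tibble: 12 × 5
   method   channel     mean_psnr sd_psnr     n
   <chr>    <chr>           <dbl>   <dbl> <int>
 1 median3d endothelial      31.8    2.68    90
 2 raw      endothelial      28.2    3.03    90
 3 vst2d    endothelial      37.1    2.80    90
 4 vst3d    endothelial      37.5    2.65    90
 5 median3d fibril           27.7    2.71    90
 6 raw      fibril           19.3    3.02    90
 7 vst2d    fibril           29.4    2.03    90
 8 vst3d    fibril           30.1    2.01    90
 9 median3d tubule           30.6    1.95    90
10 raw      tubule           24.1    4.70    90
11 vst2d    tubule           34.1    4.35    90
12 vst3d    tubule           34.9    4.46    90
```

Reading the summary: each row is the mean ± sd of the per-slice PSNR (dB)
against the averaged ground truth, over `n` slice comparisons. Raw PSNR is
highest for the bright endothelial channel and lowest for the sparse fibril
channel; every denoiser improves on raw, the volumetric VST filter leads,
and the Median-3D baseline trails the VST variants — it smooths the noise
but erodes fine structures (thin processes, puncta, fibrils).

The same stages are scriptable from the shell via `exec/ivmproc`
(`simulate`, `denoise`, `drift-correct`, `register3d`, `benchmark`, and
`run` for YAML-configured pipelines with a JSON provenance record).

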