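---
title: "Processing intravital 2-photon stacks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing intravital 2-photon stacks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivmproc)
```

ivmproc processes multichannel intravital 2-photon microscopy data through
four stages: denoising of Poisson-Gaussian detector noise, drift correction of
time series and z-stacks, landmark-based rigid registration of serial imaging
sessions, and quantitative benchmarking against an averaged ground truth.
Every stage operates on the same container, a `stack5d`: a `(t, z, c, y, x)`
intensity array with physical calibration (voxel size in µm, frame interval in
s). This vignette describes the underlying models, the tunable parameters and
their defaults, the synthetic phantom that the tests run on, and the numerical
conventions that matter when comparing results.

## The detector noise model

Photon-counting detectors produce intensities well described by
$z = \alpha p + n$, with $p \sim \mathrm{Poisson}(y)$ the photon count,
$\alpha$ the gain in ADU/photon, and $n \sim N(\mu, \sigma^2)$ additive
read-out noise in ADU. The first two moments are
$E[z] = \alpha y + \mu$ and $\mathrm{Var}[z] = \alpha^2 y + \sigma^2$ — the
variance depends on the signal, which is what breaks plain Gaussian
denoisers on raw data. `pg_model()` holds $(\alpha, \sigma, \mu)$ and
parameterizes both the phantom corrupter (`corrupt()`) and the
variance-stabilizing transform.

## Variance-stabilized denoising

`denoise_vst()` composes four steps per channel:

1. **Noise estimation.** `estimate_noise_sigma()` computes the median absolute
   deviation of a $3\times3$ Laplacian pseudo-residual, scaled to an unbiased
   Gaussian standard deviation. The Laplacian annihilates locally planar
   structure and the MAD discounts the sparse large residuals at edges, so the
   estimate tracks the noise floor rather than image content. In volumetric
   (`vst3d`) mode the estimate is made once per channel on a tiled mosaic of
   up to 10 slices evenly spaced through the stack (`build_estimation_tile()`)
   — pooling slices stabilizes the estimate; in slice-wise (`vst2d`) mode each
   image is estimated on itself.
2. **Stabilization.** The generalized Anscombe transform
   $f(z) = \tfrac{2}{\alpha}\sqrt{\alpha z + \tfrac{3}{8}\alpha^2 + \sigma^2 -
   \alpha\mu}$ maps the data to approximately unit-variance Gaussian noise for
   photon means of roughly 20 and above (`gat_forward()`); non-positive
   radicands clamp to 0. The stabilized data are then linearly rescaled to
   $[0, 1]$ (`rescale_unit()`), and the filter is told the rescaled noise
   level `1 / (max - min)`.
3. **Collaborative filtering.** `collaborative_filter()` is a two-stage
   block-matching patch filter: similar patches (8×8 pixels in 2D, 4×4×4
   voxels in 3D) are grouped within a bounded search window, transformed by a
   separable orthonormal DCT across the patch and a Walsh–Hadamard transform
   along the group, and hard-thresholded at $\lambda \sigma$ with
   $\lambda = 2.7$; a second pass regroups on the first estimate and applies
   empirical Wiener shrinkage. Overlapping estimates are aggregated by
   weighted averaging (weights inversely proportional to the retained
   coefficient count, respectively the Wiener energy). It is a faithful
   member of the patch-grouping/transform-shrinkage family rather than a
   bit-exact clone of any published binary; the Gaussian-domain core is
   deliberately pluggable (`filter_backend = "identity"` exists for pipeline
   diagnostics).
4. **Inversion.** The result is mapped back through the inverse transform and
   re-quantized to the acquisition bit depth (round half away from zero,
   clipped, clip counts logged). Two inverses are provided: `algebraic`
   (exactly inverts the forward map — correct for large counts) and
   `exact_unbiased` (default), the closed-form approximation of the exact
   unbiased inverse of the Anscombe transform,
   $I(D) = D^2/4 + \sqrt{3/2}\,D^{-1}/4 - \tfrac{11}{8}D^{-2} +
   \tfrac{5}{8}\sqrt{3/2}\,D^{-3} - \tfrac18$, generalized to
   $(\alpha,\sigma,\mu)$ by the unit-gain substitution and the
   $-(\sigma/\alpha)^2$ variance correction. The unbiased inverse removes the
   systematic darkening of low-count regions that the algebraic inverse
   produces when applied to a filtered (i.e. averaged) stabilized value.

Volumes are filtered in overlapping chunks of 10 slices, advancing by 5
(`chunk_plan()`), so that memory stays bounded and chunks could be distributed
across workers. The merge convention is ownership, not blending: each frame is
written by exactly one chunk, the one whose centre is nearest (a frame exactly
between two chunk centres goes to the earlier chunk). This makes the merge
deterministic and partition-testable; cross-fade blending would hide chunk
seams slightly better but makes results depend on chunk layout in a way that
is hard to verify.

The Median 3D baseline (`median3d()`) replaces each voxel with the median of
its $(2r+1)^3$ neighbourhood, truncated at the borders. The conventional
"sigma = 2 per dimension" phrasing of the common FIJI plugin is interpreted
as the per-axis **radius** — a median filter has no sigma — giving the 5×5×5
default window.

If no `pg_model` is supplied, the pipeline uses unit gain, zero offset and
the estimated sigma; supplying a calibrated model refines the stabilization
at low counts.

## Drift correction

`register_2d()` follows the registration-channel strategy: all detection
channels are summed in 32-bit float, each frame is contrast-stretched
(`enhance_contrast_frame()`, 1% total saturated pixels, interpreted as 0.5%
per histogram tail — the symmetric reading of an ambiguous convention), and
the result is quantized back to the input depth. Summing concentrates the
features of all channels in one image, which matters when individual channels
are sparse.

Translation estimation is feature-based: a multi-scale difference-of-Gaussian
pyramid (initial blur 1.5 px, 3 steps per octave, octaves bounded between 64
and 512 px) yields keypoints with sub-pixel quadratic localization and an
edge-response rejection on the principal-curvature ratio. Descriptors are
normalized intensity patches sampled on an 8×8 grid scaled with the keypoint's
blur level — for a translation-only model between consecutive frames of the
same modality, rotation- and illumination-invariant gradient histograms add
cost without benefit, so the descriptor is deliberately this simple. Matching
uses nearest-neighbour search with a 0.92 ratio test; the translation is the
largest consensus set (inlier radius 3 px, at least 7 inliers), refined to
sub-pixel precision by a parabolic fit of the local normalized
cross-correlation around the integer shift, with the translation's own
zero-fill band excluded from the correlation window (including it biases the
parabola by ~0.1 px). Pairwise shifts are composed to frame 1 (`sequential`
mode); a `fixed_ref` mode matches every frame directly to frame 1 and avoids
error accumulation for long series with slow drift — which composition the
original workflow used is not documented, so both are provided.

A pair with too few inliers never aborts a series: its relative shift falls
back to `(0, 0)` and the frame is flagged in the returned series — batch
processing must survive a single featureless frame. `apply_translations()`
shifts every channel by bilinear interpolation with zero fill and re-quantizes
integer inputs.

## Rigid serial registration

`fit_rigid()` estimates the transform $p_{ref} = R\,p_{mov} + t$ minimizing
$\sum_i \lVert R m_i + t - r_i \rVert^2$ over active landmark pairs by the
SVD (Kabsch) procedure with determinant correction; the orthonormality of $R$
is asserted on every call. Landmarks live in physical µm coordinates and use
the BigWarp CSV export dialect, so points placed in that GUI can be reused
directly. Fewer than 3 active pairs, or collinear moving points, raise a
degenerate-configuration error; 10–20 landmarks is the practical range.

`resample_volume()` pull-samples the moving volume at the inverse-transformed
position of every reference voxel centre, by trilinear interpolation in
physical coordinates (anisotropic voxels handled naturally), zero outside.
Trilinear rather than spline interpolation keeps intensities non-negative and
bounded by the local data — a property worth more than the extra smoothness
here. Only rotation + translation is fitted, deliberately: similarity, affine
or deformable warps can absorb genuine biological size and shape changes
(tissue shrinkage after injury) into the registration, which is exactly what
serial imaging is supposed to reveal.

`align_replicates_translation()` handles the simpler intra-session case:
replicates of one volume are aligned to the first by the integer peak of the
FFT cross-correlation of channel-summed volumes plus a per-axis quadratic
sub-voxel refinement — rotation-free alignment is all the replicate
acquisition needs, and it is fast at any volume size.

## Ground truth and benchmarking

`generate_ground_truth()` averages aligned replicates voxelwise: for $n$
replicates with additive zero-mean noise the averaged volume's noise variance
drops $n$-fold, a PSNR gain of $10\log_{10} n$ dB (13.98 dB at $n = 25$),
which the tests verify. `image_metrics()` computes MSE-derived metrics per
slice; PSNR uses the per-slice maximum of the reference as peak by default,
with a fixed-peak (`peak_value = 2^{bits}-1`) alternative, since the peak
convention of measurement plugins varies and the choice shifts absolute dB
values (not method orderings). Metrics are computed per slice, not per
volume, and against the quantized ground truth, because denoised outputs are
themselves re-quantized. `benchmark_denoisers()` runs any set of denoiser
callables (plus the raw input) over all time points, slices and channels and
returns tidy per-slice rows and per-(method, channel) summaries;
`plot_psnr()` shows the distribution as boxplots.

## The synthetic phantom

`make_phantom()` builds the deterministic scene that all tests and the
bundled benchmark run on; it emulates the structure of a renal intravital
validation acquisition with three channels:

- **endothelial** (bright): a network of random-walk filaments, two thirds at
  capillary scale (~8 µm FWHM cross-section) and one third thin cellular
  processes (~2.8 µm);
- **tubule** (intermediate): hollow tubes whose wall thickness (~6 µm)
  matches tubular epithelium, plus a requested number of well-separated
  bright puncta (~3 µm, lysosome-like), each an isolated local maximum —
  their count is testable by thresholded connected components;
- **fibril**: thin (~2.4 µm) oriented filaments confined to the top slices,
  like capsular collagen seen by second-harmonic generation, over dim tubular
  autofluorescence spanning the volume — bright structures, but sparse and
  fine, which is what makes this the worst channel for every denoiser.

All channels sit on a smooth parenchymal "bed" — a coarse random field
upsampled trilinearly, at 35% of the channel amplitude over a 20 ADU
baseline — because real kidney frames are filled with tissue
autofluorescence, not line art on black; the bed is what makes a plain median
filter competitive on smooth regions, exactly as on real data. Structure
widths are specified in µm and converted through the voxel size, so phantoms
at different resolutions stay anatomically comparable. Amplitudes default to
1200/500/350 ADU, chosen so that under the default acquisition noise the
per-channel raw PSNR ladder matches what renal validation recordings show:
endothelial channel best, fibril channel worst — worst not because its signal
is dim but because it is sparse and fine-grained.

The default geometry is `(25, 45, 3, 256, 256)` at `(1.2, 1.15, 1.15)` µm —
25 replicate time points of a 45-slice volume, i.e. 1,125 slice pairs for the
benchmark. The replicate generator's default noise model is
$\alpha = 4$ ADU/photon, $\sigma = 10$ ADU: the high-gain, low-power corner
of realistic detector settings, matching the *intentionally noisy* character
of a denoising validation acquisition. Detector gains of real systems are
rarely published; 1–4 ADU/photon and 2–10 ADU read noise bracket common
GaAsP/PMT configurations, and the defaults sit at the noisy end of that
bracket by design.

Everything the generator produces is a pure function of `(spec, seed)`; one
global seed expands to per-stage child seeds through a fixed linear schedule
(`ivmproc:::child_seed`), so replicate sets, landmark samples and noise
fields are individually reproducible.

What the phantom does **not** emulate: the optical point-spread function and
depth-dependent scattering/attenuation, flow and motion within a frame
(line-by-line breathing artefacts), bleaching other than the optional
mono-exponential channel-1 decay, spectral bleed-through between channels,
and spatially correlated (striping) detector noise. Tests passing on the
phantom therefore demonstrate algorithmic correctness under the stated noise
model and geometry — not performance claims on any particular real
acquisition.

## Problem sizes used by the test suite

The suite keeps the validation study's *shape* where the shape is the point —
the replicate benchmark runs 25 time points × 45 slices × 3 channels, so the
per-channel row count is the canonical 1,125 — while using a 64×64-pixel
(~74 µm) field of view with structure counts matching that smaller window
(2 tubules, 6 filaments, 5 puncta, 10 fibrils). Unit tests use smaller
volumes still. These sizes are the package's choice of a desk-scale
configuration; all of them are parameters, and the full-scale defaults are a
single argument away.

## Numerical conventions and edge cases

- Axis order is `(t, z, c, y, x)`; 1-based indices in R; voxel centres at
  integer grid positions; physical position = (index − 1) × voxel size.
- Quantization rounds half away from zero and clips to the bit-depth range,
  logging clip counts. Base R's round-half-to-even is *not* used.
- `rescale_unit()` on a constant array returns zeros plus a degenerate flag;
  the inverse restores the constant.
- GAT radicands ≤ 0 map to 0; inverse outputs below 0 clip to 0; the
  exact-unbiased inverse clamps its argument at the transform's minimum
  $2\sqrt{3/8}$.
- TIFF storage: multi-page TIFF with a JSON sidecar
  (`voxel_size_um`, `frame_interval_s`, `channel_names`, axis extents).
  8/16-bit stacks round-trip bit-exactly; 32-bit intermediates are stored
  range-scaled on the uint32 grid (relative error ~2⁻³²).
- Chunk keep-ranges partition the frame axis exactly; equidistant frames go
  to the earlier chunk.
- The drift estimator never aborts on a featureless pair; it flags and
  continues.

## Known limitations

- The collaborative filter is tuned for correctness and determinism, not for
  matching any reference implementation's output bit-for-bit; plugging an
  external reference backend in as a cross-check is possible through the
  module boundary but not bundled.
- Whether "rigid" registration in common GUI workflows includes isotropic
  scaling is ambiguous; `fit_rigid()` is pure rotation + translation, so
  landmark sets exported from a similarity fit will show a residual scale
  error rather than silently absorbing it.
- Sub-pixel drift accuracy degrades on frames whose texture is concentrated
  near the zero-filled border, and the sequential composition accumulates
  error over very long series — `fixed_ref` mode is the remedy when drift is
  slow.
- `read_stack()` does not parse OME-XML metadata from third-party OME-TIFFs;
  without a sidecar it assumes a single-channel z-stack and warns.
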