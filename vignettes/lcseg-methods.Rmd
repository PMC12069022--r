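---
title: "Automated locus coeruleus analysis: models, phantoms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated locus coeruleus analysis: models, phantoms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The locus coeruleus (LC) is a paired noradrenergic nucleus in the upper pons,
roughly 2 mm across and 12-15 mm long, that appears hyperintense on
neuromelanin-sensitive FLASH MRI. Its contrast against the surrounding
pontine tegmentum is a candidate biomarker of noradrenergic integrity in
aging and Alzheimer's disease. Quantifying it by hand is slow and
rater-dependent, and the structure is so small that every step — finding it,
delineating it, choosing a reference region, reducing it to scalar features —
needs care. `lcseg` implements a fully automatic pipeline:

1. **Localization**: a tiny 3D U-Net sees the whole volume block-averaged by
   a factor of 4 and predicts a (dilated) LC probability map. Five such nets,
   trained on different validation splits, are averaged voxel-wise; the
   average is thresholded at 0.5 and the two largest connected components
   give the left and right candidate centers.
2. **Segmentation**: a second U-Net of the same architecture sees a single
   64^3-voxel patch covering both LCs, re-normalized to zero mean and unit
   (population) SD. Each of five members produces a probability map,
   thresholded at 0.5; the five hard masks are combined by per-voxel
   majority vote (label 1 iff at least 3 of 5 agree — no ties with five
   voters).
3. **Reference region**: an LC-oriented orthonormal frame is computed from
   the two predicted masks alone; reference boxes are placed at a mean
   offset learned in that frame on training data.
4. **Features**: maximum and median contrast ratios, subregional contrast
   ratios (halves and thirds along the axial dimension), signal length and
   volume, each per hemisphere and bilaterally averaged.

## The coordinate frame

With `l1`, `r1` the first principal axes of the left/right LC voxel clouds
(world coordinates, sign fixed to point superior) and `c_l`, `c_r` the
centers of mass:

    v1 = normalize((l1 + r1) / 2)        # rostrocaudal
    v2 = normalize((c_l - c_r) x v1)     # approximately anterior
    v3 = v1 x v2                          # approximately right-to-left
    origin = (c_l + c_r) / 2

The mean of two unit vectors and a cross product are not unit length, so v1
and v2 are explicitly re-normalized; the basis is then orthonormal and
right-handed by construction. Because every ingredient is defined in world
coordinates from the masks themselves, the frame rotates with the head: a
reference offset learned in frame coordinates lands in the same anatomical
spot regardless of head rotation, with no pons segmentation and no
registration. The sign conventions (principal axes point superior;
left-minus-right in v2) are arbitrary but fixed, and learned offsets are
averaged per hemisphere separately, not mirrored.

Degenerate geometry (fewer than 3 mask voxels, coincident centroids,
anti-parallel principal axes) raises a typed error; `learn_offset()` skips
such training samples with a warning.

## Features

Contrast ratios follow the standard definition
`CR = (stat(LC) - median(REF)) / median(REF)` with `stat` either max or
median; medians of even counts average the two central values. Subregional
CRs split the occupied axial slice range `s_min..s_max` (`S` slices, interior
gaps included) at `s_min + round(S j / n)` (round half away from zero),
giving contiguous caudal-to-rostral sections whose slice counts differ by at
most one. Length is the number of occupied axial slices times the axial
voxel size (gaps do not contribute); volume is voxel count times voxel
volume. "Axial" always means the grid axis whose world direction is closest
to inferior-superior, read from the affine — never a fixed array axis.
Bilateral features are unweighted means of the two hemispheres; if one
hemisphere is empty the bilateral value falls back to the other side and is
flagged `partial`.

## The phantom generator: what it emulates, and what it does not

Real LC-protocol acquisitions are not publicly deposited, so the package
ships a synthetic phantom generator that states the world the tests live in:

- grid 64^3 at 0.375 mm (the working resolution after 2x sinc upsampling of
  0.75 mm acquisitions; a 24 mm field of view around the pons);
- a pons-like smooth ellipsoid (plateau intensity 100, darker surround);
- two near-cylindrical LC tubes, 2 mm diameter, 7.5 mm long, 8 mm apart,
  with a gentle 0.5 mm outward bow; hard rasterized masks (a voxel belongs
  iff its center is within one radius of the center-line), but intensity
  softened by a one-voxel Gaussian to mimic partial-volume blur;
- peak contrast ratio `true_cr` (default 0.2, in the range reported for
  healthy adults): after the blur, the LC additive component is rescaled so
  the maximum over mask voxels is exactly `true_cr x background`, making
  `true_cr` the generator's *definition* of peak CR rather than an
  approximate target;
- multiplicative bias field: the sum of 3 random low-order cosine modes in
  scanner coordinates, scaled to a 10% peak-to-trough default (residual
  inhomogeneity after imperfect bias correction);
- additive Gaussian noise, default sigma = 2% of background (high-SNR FLASH;
  at such SNR a Rician magnitude distribution is indistinguishable from
  Gaussian, so Gaussian is used);
- rigid head rotation up to +-10 degrees per axis (to +-20-30 degrees in the
  robustness tests), applied by evaluating the analytic geometry at
  back-rotated voxel centers so that truth masks are rasterized on the
  rotated grid, never interpolated;
- reference boxes (3 x 3 mm cross-section, 5 mm along v1) planted at frame
  offsets (0, -6, +2) mm left and (0, -6, -2) mm right — medial-ventral to
  each LC inside the tegmentum plateau. The two hemispheres need distinct
  centers in the shared frame, hence the mirrored v3 component.

What it does **not** emulate: surrounding anatomy (fourth ventricle,
cerebellum, vessels), motion artifacts, slab acquisitions, multi-site
protocol differences, or realistic LC intensity distributions (a
plateau-with-blurred-edges model is assumed). A green phantom test
establishes that the machinery is correct and self-consistent — not that the
trained toy ensemble would segment clinical data.

## Training: what is scaled down and why

The networks are tiny 3D U-Nets (depth 2, base 8 channels, two
conv(3x3x3) -> instance-norm -> ReLU units per level, max-pooling,
nearest-neighbor upsampling with skip concatenation, sigmoid output)
written directly in C++ (BLAS-backed
shifted-GEMM convolutions with hand-derived backpropagation, verified
against finite differences in the test suite). Training uses Adam with
gradient accumulation, best-validation-loss checkpointing and early stopping
after `patience` epochs without improvement; with a fixed seed and one BLAS
thread it is bit-reproducible.

Design choices that deviate from the obvious defaults, with reasons:

- **Loss**: soft-Dice plus *positive-class-weighted* binary cross-entropy.
  The LC occupies ~0.3% of a 64^3 patch; with plain mean BCE the background
  term dominates and, in the few hundred optimizer steps a CPU budget
  allows, the net collapses to the empty prediction. A moderate fixed
  positive weight (default 10) balances recall pressure against the Dice
  term; very large weights (e.g. the raw class ratio ~300) overshoot into
  massive over-segmentation and converge slower.
- **Instance normalization** after every block convolution (the nnU-Net
  standard). Without it the raw conv stack needs thousands of optimizer
  steps to tighten the segmentation boundary and remains sensitive to the
  per-sample intensity scale left by the bias field; with it the acceptance
  experiment's five-member ensemble reaches a mean held-out bilateral Dice
  around 0.9 within three epochs at learning rate 1e-2 (computed in
  `tests/testthat/test-acceptance.R`, criterion 7).
- **No training augmentation**: intensity jitter would be erased by the
  per-patch z-scoring (the pipeline is provably invariant to affine
  intensity maps), and rotation variability is already generated by the
  phantom sampler's random rigid rotations — augmenting on top would double
  CPU cost for redundant variance.
- **Localization target**: the LC union dilated by 2 working-grid voxels,
  then block-max downsampled. The raw target at 1.5 mm grid resolution is
  1-2 voxels wide, which makes thresholded components unstable; dilation
  stabilizes them without moving their centroids.
- **One bilateral patch** centered at the midpoint of the two localization
  centers (rather than one patch per hemisphere): simpler, and the 64^3
  patch comfortably covers both LCs plus context at 0.375 mm.
- **Localization fallback**: if thresholding yields a single connected
  component it is split at its left-right world midpoint and flagged in the
  QC record; zero components mark the result as failed rather than erroring.

The end-to-end experiment in the acceptance suite trains 5 members per stage
on 40 phantoms and evaluates 10 held-out phantoms. To fit the whole test
suite in a CI-scale CPU budget the experiment uses few epochs (the task —
bright tubes on a dark background after normalization — converges in tens of
Adam steps) and small members; this is a deliberate scale-down of the
original design (GPU-scale nnU-Net-style training), which the package does
not attempt to reproduce.

## Evaluation conventions

- DSC = 2|X∩Y| / (|X|+|Y|); the bilateral DSC of a subject is the mean of
  the two hemisphere DSCs, not the DSC of the union. Two empty masks yield
  DSC 1 with a warning (agreement on absence), configurable to an error; the
  situation does not arise in normal use.
- The accuracy metric is the mean of voxel sensitivity and specificity.
- Probabilistic templates average pre-aligned binary masks; binarization at
  50% is *inclusive* (a voxel covered by exactly half the masks, possible
  with an even count, is included: the threshold test is
  `p > 0.5 - 1e-12`). Spatial normalization is out of scope — the template
  operations start from masks already on a common grid.
- Cohen's d uses the pooled sample SD.

## Numerical choices and edge cases

- Sinc upsampling is Fourier zero-padding (the exact trigonometric
  interpolant): band-limited inputs are reproduced exactly, the DC bin —
  hence the volume mean — is preserved, and Nyquist bins of even-sized axes
  are split at half weight so the output stays real. Edge ringing on
  non-periodic content is accepted as ideal-sinc behavior. The windowing of
  the original acquisition pipeline's sinc filter is unspecified; the ideal
  interpolant is the assumption.
- All voxel indices are 0-based; world coordinates are RAS through the
  affine. Left/right is always decided in world space, never by grid index.
- NIfTI: volumes are written as float64 (bit-exact round-trip), masks as
  uint8; the affine lives in the float32 sform, so it round-trips to ~1e-6
  only for coordinates up to ~16 mm in magnitude (true for all
  package-generated data). NIfTI-1 and NIfTI-2, plain or gzipped, little or
  big endian are read; scl_slope/inter scaling is applied; 4-D images are
  rejected.
- Member probability threshold 0.5 before voting (hard votes, as "majority
  vote" implies); the localization average is likewise thresholded at 0.5.
- Components smaller than 3 voxels are dropped before hemisphere assignment
  during inference only (speckle would otherwise corrupt the length/volume
  features); `split_hemispheres()` itself defaults to keeping everything so
  the partition property `left ∪ right = input` holds.
- Non-isotropic voxels are accepted with a warning; every mm conversion uses
  per-axis sizes.
- Offsets are stored in mm (not voxels) for resolution independence.

## Known limitations

- The trained toy ensembles are phantom-scale demonstrations; no claim is
  made about transfer to clinical acquisitions or other MRI protocols.
- The generator's LC intensity model (plateau + Gaussian blur) is a guess at
  the true FLASH profile; features that depend on the intensity
  *distribution* inside the LC (cr_median) are exactly recoverable only in
  the noise-free setting.
- `split_rostrocaudal` sections follow grid-axial slices (consistent with
  the length definition), not the frame axis v1; for rotations within the
  tested +-20-30 degrees the difference is at most one slice per boundary.
- Rotation equivariance of the frame is rasterization-limited: components
  agree to ~1e-3, not machine precision.
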