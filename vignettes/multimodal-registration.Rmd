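---
title: "Multimodal plant image registration with combined feature-point detectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal plant image registration with combined feature-point detectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytoreg)
```

## The problem

High-throughput plant phenotyping installations image every plant in
several modalities: visible light (VIS) shows the full optical scene —
plant, pot, carrier, walls, shadows and an inhomogeneous illumination
field — while fluorescence (FLU) shows essentially only the
chlorophyll-containing tissue on a near-black background. Because the two
cameras sit in different photo-chambers, have different resolutions and
the plants move between acquisitions, every FLU/VIS pair must be aligned
anew before the modalities can be analysed jointly (for example, using the
high-contrast FLU segmentation to guide segmentation of the difficult VIS
image).

`phytoreg` registers such pairs by feature-point (FP) matching: detect
interest points in both images, describe their local neighbourhoods,
match descriptors, and estimate a 2D affine transform robustly from the
putative correspondences. Its design follows the empirical finding that
no single detector works for all plant habits (round rosette leaves in
top view versus thin curved cereal leaves in side view), so several
detectors are run and their outputs merged into one feature list, and
that structural pre-processing — background masking and in particular a
colour-edge transform — makes the two modalities far more similar and is
often the difference between failure and success.

## Pipeline and model

`register_pair()` chains six stages:

1. **Pre-processing.** Optional ideal background filtering with a supplied
   plant mask (`mode = "masked"`), rendering as plain luminance greyscale
   or as a *colour-edge* image, and optional cropping to the plant
   bounding box. The colour-edge image is the per-channel Sobel gradient
   magnitude reduced across channels by the maximum and rescaled to peak
   at 1. It is exactly invariant to constant intensity offsets, which
   removes the smooth vertical illumination gradient of VIS backgrounds.
2. **Detection.** Five native detectors with a uniform contract
   (subpixel `x`, `y`, `scale`, `strength`): Harris and minimum-eigenvalue
   corners on a Gaussian-smoothed structure tensor (window 3, k = 0.04),
   FAST segment-test corners (9 of 16 contiguous circle pixels, contrast
   0.1), determinant-of-Hessian blobs over a 4-octave scale pyramid, and
   MSER regions from a quantised threshold sweep (step 0.8 grey levels)
   run on the image and its inversion. `detect_combined()` concatenates
   any subset and merges near-duplicates (< 1 px apart, scale ratio
   < 1.2), keeping the stronger point. BRISK/KAZE-style detectors can be
   plugged in through `register_adapter()`; they are deliberately not
   reimplemented, since the combined scheme only needs the uniform
   feature-point contract.
3. **Description.** One descriptor for all detectors: a
   `4 * max(scale, 2.5)` px patch resampled to 16×16, 4×4 cells of 4-bin
   gradient-orientation histograms, L2-normalised (64 values). A shared
   descriptor is required for merged feature lists to be mutually
   matchable; orientation normalisation is omitted on purpose because
   plants are imaged upright and admissible rotations are small.
4. **Matching.** Squared-difference nearest neighbours with three
   acceptance constraints: distance at most 15% of the maximal possible
   distance, best/second-best ratio at most 0.75, and one-to-one
   uniqueness (smallest distance wins). All three default values are the
   "adjusted" parameter set that favours more candidate matches; the
   geometric verification that follows is what removes the false ones.
5. **Robust estimation.** RANSAC over exact 3-pair affine solutions
   (3 non-collinear pairs are the minimum that determines the 6-dof
   transform), inlier tolerance 10 px, adaptive trial bound
   `log(1 - 0.95) / log(1 - w^3)` capped at 5000 trials, fully
   deterministic given the seed. The consensus set is then locally
   optimised: three Huber-weighted least-squares iterations followed by an
   iterated trimmed refit on the best half of the residuals (never fewer
   than 12 pairs). The generous 10 px tolerance is needed to *find* the
   consensus between modalities, but correspondences near that tolerance
   carry several pixels of localisation noise; a plain least-squares refit
   over all of them measurably biases the recovered scale (and hence the
   translation), while the trimmed refit roughly halves the median
   translation error in our synthetic recovery suite.
6. **Validation.** The estimate is decomposed (rotation from the polar
   factor, scales from the triangular remainder; recomposition is exact
   to 1e-9) and checked against admissibility bounds: axis scales in
   [0.4, 2.5], |rotation| ≤ 20°, translation ≤ half the VIS diagonal.
   Out-of-bounds transforms are reported as registration *failure* —
   success additionally requires at least 3 selected pairs.

Coordinates are 0-based pixel centres with x = column and y = row,
everywhere; the transform maps FLU coordinates into the VIS frame.

## Evaluation framework

Two metrics summarise a benchmark run. The success rate `SR = n_s / n` is
the fraction of attempted pairs that produced an admissible transform.
The overlap ratio `OR = a_r / a` quantifies accuracy: the fraction of
ground-truth VIS plant area covered by the warped FLU *plant region*
(not the full FLU frame — misaligned leaves should cost overlap).
`enumerate_configurations()` spans the full factorial design
(original/manual segmentation × greyscale/colour-edge × full/cropped ×
detector), which for seven single detectors plus the combined one yields
the 64-configuration grid; `run_benchmark()` produces one record per
(pair, configuration) with the characteristic counts — detected FPs in
VIS and FLU, putative pairs, finally selected pairs — and
`summarize_benchmark()` averages those counts *over successful
registrations only*, alongside SR and mean OR.

## The synthetic scene generator

Real phenotyping datasets of this kind are proprietary, so the package
ships a generator whose samples reproduce the structural properties that
make the problem hard, with exact ground truth:

- **VIS frame** (default 514×614 px): a strictly monotone vertical
  illumination gradient, 2–5 rectangular/circular clutter shapes (pot and
  carrier analogues), a soft shadow (Gaussian-blurred, offset silhouette
  at 30% opacity), and the plant drawn last in textured green tones,
  plus Gaussian pixel noise (sd 0.02).
- **FLU frame** (default 308×406 px): the same plant silhouette alone,
  red-dominant on a near-black background (sd 0.01), positioned through
  the inverse of the ground-truth transform.
- **Plants** are unions of quadratic-Bezier strokes with tapering width:
  a top-view rosette (8 round leaves, width 20–34 px) or a side-view
  cereal shoot (vertical stem, 5 arching leaves, width 16–24 px).

The default frame sizes are quarter-scale versions of the camera
resolutions of typical large-plant installations, preserving the
VIS/FLU resolution-ratio challenge while keeping test runtimes small.
`sample_transform()` draws ground-truth transforms from the geometry such
installations actually exhibit — overall scale 1.2–1.8 (the camera
resolution ratio), ≤ 2% scale anisotropy, ±5° rotation, slight shear,
and a translation keeping the plant within ±25 px of the FLU frame
centre: the two cameras are nominally aligned, and the residual transform
drifts with temperature, plant size and carrier rotation rather than
being arbitrary. All of these are inside the admissibility envelope by
construction.

Cereal leaf widths deserve a note: the default is maize-like
(16–24 px at quarter scale, matching a few centimetres of real leaf).
Much thinner, wheat-like leaves (< 10 px) cannot satisfy the generator's
own mask-consistency contract (warping the FLU mask by the ground truth
must overlap the VIS mask with IoU ≥ 0.95), because binary rasterisation
at two resolutions differing by 1.2–1.8× already disagrees on a
half-pixel boundary band that dominates thin structures. This is a
limitation of the fixture, not of the registration method.

What the generator does *not* emulate: photometric cross-talk between
modalities, specular reflections, depth-dependent scale variation across
the plant, non-uniform backgrounds beyond the vertical gradient, and
growth. Passing the synthetic suites therefore demonstrates the
pipeline's geometric and algorithmic correctness under realistic
*structure*, not photometric robustness on any particular real camera.
`perturb_nonrigid()` adds the one failure mode repeatedly seen in
practice — inertial motion of a single leaf between acquisitions — by
redrawing one leaf in the FLU rendering with its tip displaced along the
leaf normal; the ground-truth transform is left unchanged, so a perfect
global registration shows OR < 1, exactly as real non-rigid cases do.

## Numerical choices and degenerate inputs

- Convolutions use replicate borders; corner responses within a
  half-window (plus one pixel) of the border are discarded.
- Peak locations are refined by 1D quadratic interpolation, clamped to
  ±0.5 px; strengths are reported at the grid peak.
- The determinant-of-Hessian pyramid uses base sigma 1.6 with five layers
  per octave at ratio `2^(1/3)`; maxima are taken only on the three
  interior layers, whose absolute scales tile the scale axis without
  gaps across octaves. Responses are scale-normalised by sigma^4, so the
  default response floor (25 on the squared 8-bit scale, i.e. `25/255^2`)
  is resolution-independent.
- MSER stability is the relative area change across one quantisation step
  each way; regions must be local minima of that variation along their
  component-tree branch, within 0.25 variation, 30 px to 1% of the image
  in area, and at least 20% larger than the previously accepted region on
  the same branch.
- Constant images yield no detections anywhere (zero structure tensor,
  no segment-test contrast, no extremal-region boundary); flat descriptor
  patches yield the zero vector rather than dividing by zero.
- Collinear minimal samples are rejected inside RANSAC; if every sample
  is collinear the estimator raises a degenerate-geometry error, which
  `register_pair()` converts to `success = FALSE`.
- Ties in `strongest()` and in the combined-detector merge are broken by
  (y, x) lexicographic order so results are reproducible.

## Problem sizes used by the test-suite

The shipped suites run entirely on generated data: the recovery suite
registers 50 seeded scenes (alternating rosette and cereal) and requires
at least 90% success with median errors below 0.05 in scale, 1° in
rotation and 3 px in translation; the detector-comparison suite registers
20 scenes under combined/greyscale, combined/colour-edge and each single
detector with colour-edge, and checks the two directional findings —
colour-edge does not reduce the success rate, and the combined detector
is at least as successful as the best single one. The acceptance script
(`scripts/acceptance.R`) re-derives the estimator's 3-pair minimum and
re-runs a 10-scene benchmark from scratch.

## Known limitations

- The transform class is affine; genuinely non-rigid leaf motion is
  detected only indirectly through reduced OR.
- Descriptors are not rotation- or strongly scale-invariant; the method
  targets the small admissible pose envelope of fixed camera
  installations.
- Parameter defaults were chosen for plant shoots imaged against
  controlled backgrounds and will need re-tuning for other scenes.
- MSER on heavily textured greyscale images produces many small unstable
  regions; the area and variation limits keep this in check but cost
  recall on very small plants.
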