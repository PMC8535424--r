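---
title: "Methods: registration, averaging and change analysis of OCTA en-face stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: registration, averaging and change analysis of OCTA en-face stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octava)
```

## The problem

Optical coherence tomography angiography (OCTA) renders retinal blood flow
as en-face images of the capillary plexuses. A single acquisition carries
substantial background noise, interruptions in vessel walls, and motion
artifacts. Averaging several sequential acquisitions suppresses noise, but it
raises two questions this package is built to answer quantitatively:

1. **Repeatability** — how consistent are vessel-density (VD) measurements
   across repeated acquisitions of the same eye?
2. **Gain vs loss** — does averaging only *add* capillary signal (by filling
   interruptions and recovering weak capillaries), or can it also *erase*
   vessels that are visible in a single acquisition?

Because sequential acquisitions are misaligned by eye motion, averaging
requires registration first; because thresholded difference maps are noisy,
change is judged per region (a 3x3 grid of 172x172-pixel boxes on the
standard 516x516 raster) rather than per pixel.

## Pipeline

For each eye, scan area (3x3 or 6x6 mm) and slab (superficial plexus SVP,
deep complex DVC, or full retina):

1. `crop_logo()` removes the device logo band (synthetic images need no
   crop).
2. `register_linear()` aligns acquisitions 2..N to the first acquired image
   with a similarity transform (translation, rotation, uniform scale — no
   shear), minimising mean squared intensity difference under a 3-level
   Gaussian pyramid.
3. `register_elastic()` refines each frame with a cubic B-spline deformation
   field (control spacing 32 px) minimising the same metric plus a
   bending-energy penalty.
4. `average_stack()` computes the per-pixel arithmetic mean (average-intensity
   Z-projection), accumulated in real arithmetic and rounded once.
5. `diff_pipeline()` forms the positive-part difference maps
   `gain = max(averaged - single, 0)` and `loss = max(single - averaged, 0)`
   against the first acquisition, binarizes them, overlays them in red, and
   scores the 9 boxes.
6. `vessel_density()` binarizes images at an automatic threshold (Otsu by
   default) and reports vessel pixels whole-image and per box.
7. `icc()` / `repeatability_report()` quantify repeatability of the VD
   measurements across the repeated acquisitions with the intraclass
   correlation coefficient.

## Models and conventions

**Similarity transform.** `T(p) = s R(theta) (p - c) + c + t` about the image
centre `c`; resampling is an inverse warp with bilinear interpolation, and
pixels that map outside the source raster are zero-filled and flagged
invalid. Downstream pixel counts are restricted to the joint validity mask so
border fill is never scored as change. The reference frame (the first
acquisition) is returned bit-exact.

**Linear optimisation.** Mean squared difference is the metric (all frames
are the same modality); it is minimised per pyramid level with L-BFGS-B under
sanity bounds (|theta| <= 20 degrees, s in [0.8, 1.25]), after a coarse
translation/rotation grid search at the top level that secures the capture
range against false minima (bright motion stripes can otherwise attract the
optimiser). A fitted transform outside the bounds raises a registration
failure rather than returning silently; if optimisation cannot improve on the
identity, the identity is kept, so registration never increases the MSE. At
rasters above 200 px the metric is evaluated on every second pixel in each
dimension, which leaves the optimum unchanged in practice at a quarter of the
cost. The optimiser is deterministic (identity initialisation, fixed
iteration caps), so registration needs no seed.

**Elastic refinement.** Displacements are `u(p) = B_r C B_c'` with cubic
B-spline bases and a control grid of spacing 32 px. The objective is
`mean(residual^2)/2 + lambda * bending(C)` with `lambda = 0.1` by default and
the bending term a normalised squared second difference of the control
coefficients. The analytic gradient (residual times warped image gradient,
projected onto the bases) feeds L-BFGS with a 50-iteration cap. Starting from
the zero field guarantees the elastic stage never ends worse than the linear
stage. Fields whose maximum displacement exceeds 15 px (configurable) raise a
registration failure. The cap and the default `lambda` were fixed at design
time; `lambda` mainly matters at the extremes (very large values shrink the
field to zero, which is tested as a property).

**Averaging.** All frames contribute everywhere by default, including
zero-filled invalid pixels, mirroring a plain stack Z-projection;
`valid_only = TRUE` averages only the frames valid at each pixel. Rounding is
half-away-from-zero, chosen so the two-frame average of 0 and 255 is 128;
accumulation happens before the single rounding so no drift accrues.

**Difference thresholds.** Binarization of the difference maps uses
`foreground = value >= threshold`, with slab defaults of 40 (SVP, full
retina) and 60 (DVC) on the 8-bit scale — the DVC's stronger background
noise needs the higher cut to flag a comparable area. Thresholds apply
directly to the 8-bit difference values, with no rescaling in between.

**Box grading.** A box is flagged when at least `min_pixels = 50` flagged
pixels fall inside it. Expert grading has no pixel criterion; the floor
exists so single noise pixels cannot flip a presence/absence flag, and it is
exposed in every scoring function. The surrogate for expert judgement on
synthetic data restricts gain to the ground-truth vessel support (gain on
background is noise, not detection), and restricts loss to vessel support
that was perfused in *every* acquisition, eroded by one pixel: losing an
intermittently perfused capillary or an interpolation-softened vessel edge is
not an erased vessel, and human graders would not call it one.

**Vessel density.** Otsu's threshold is the default; IsoData (the classic
intermeans iteration) is offered because common "auto-threshold" tools use an
IsoData variant. Both are computed from the 256-bin histogram of the rounded
image. VD is reported as a fraction and as pixels per 172x172 box, the unit
in which box-level results are conventionally quoted. A constant image has no
histogram to split and errors; callers who want VD 0 for an empty image can
pass a fixed threshold.

**ICC.** The repeatability statistic is ICC(2,1): two-way random effects,
absolute agreement, single measurement, computed from the ANOVA mean squares,
with the 95% interval by the F-distribution method of McGraw & Wong.
Acquisitions are exchangeable "raters", and absolute agreement (not mere
consistency) is what repeatability of a quantitative biomarker requires. Each
(eye, scan area, slab) cell contributes one ICC with the grid boxes as
subject rows and the 5 acquisitions as columns. Group comparisons of ICCs use
Welch's t-test by default (no equal-variance assumption), raw p-values
without multiplicity adjustment, and stratified summaries report the mean,
SD and median.

## The synthetic-data generator

No real OCTA images ship with the package, so every downstream stage is
exercised on synthetic angiograms with known ground truth
(`synthetic_spec()`, `generate_stack()`):

- **Vasculature**: branching trunk trees (jagged recursive branches, width
  tapering 4 px to 1 px; SVP style only) over a random-walk capillary mesh
  grown until it covers the requested fraction of the raster. The DVC style
  is a denser, finer mesh without trunks.
- **Intensities**: background near 20, vessels near 180 on the 8-bit scale —
  a separation that makes the standard difference thresholds (40/60)
  meaningful; zero-mean Gaussian noise (SD 15 for healthy SVP, 20 for DVC,
  +6 for oedema) added once and clamped once to [0, 255].
- **Per-acquisition geometry**: acquisition 1 is rendered with identity
  geometry so recovery is judged against absolute ground truth; later
  acquisitions draw similarity jitter (SD 4 px translation, 2 degrees
  rotation, 1% scale; 1.5x for oedema, emulating poorer fixation) and a
  smooth elastic warp (sum of Gaussian bumps, amplitude 4 px, length scale
  48 px). The best-fit global similarity component is projected out of each
  bump field so the decomposition into "similarity jitter plus elastic
  residual" is identifiable — otherwise part of the elastic field would be an
  unlabelled extra similarity and transform recovery would be ill-posed.
- **Intermittent perfusion**: each capillary segment independently carries no
  flow signal in a given acquisition with probability `dropout_rate`
  (default 0.15) — the physiological basis for averaging *gaining* capillary
  signal. Trunks never drop out.
- **Artifacts**: full-width bright motion-stripe rows (Poisson, one per
  acquisition in expectation) applied after the geometric warp so they stay
  scan-line aligned; oedema eyes get dark cystoid regions rendered as smooth
  ellipses multiplying local intensity by 0.2--0.5.
- **Quality index**: a 0--100 signal-strength surrogate (percentile contrast
  over a background-restricted robust noise estimate) attached to every
  rendered acquisition.
- **Determinism**: everything is a pure function of (spec, seed); each
  acquisition uses a fixed seed offset so it is reproducible in isolation.

What the generator does **not** emulate: physical OCT speckle statistics,
projection artifacts between slabs, 3-D volumes, vessel-calibre-dependent
flow signal. Passing tests therefore demonstrate that the *pipeline* is
correct and behaves as the real study observed under these idealised
conditions — they do not validate the pipeline's clinical accuracy on device
images.

## Problem sizes used by the test and acceptance suites

- Registration recovery: 20 stacks of 5 acquisitions at 258x258 px (enough
  raster for the 48 px elastic length scale while keeping the suite fast);
  errors are medians over the 80 non-reference frames.
- Gain/loss cohort: 20 eyes at the full 516x516 raster (the 3x3 grid of
  172x172 boxes requires it), healthy SVP defaults: noise SD 15, dropout
  0.15.
- ICC recovery: 200 replicates of 50x5 matrices at each true ICC in
  {0.3, 0.6, 0.9}; cohort orderings over 20 seeds of 3-eye cohorts at
  129x129 px with a 43 px box grid.

## Known limitations

- The elastic model is unidirectional (no symmetric consistency term) and
  landmark-free.
- MSE is the only registration metric; it is appropriate for same-modality
  stacks but sensitive to large artifacts — the coarse grid search mitigates,
  not removes, this.
- The surrogate grader is a fixed rule, not a model of expert perception;
  agreement statistics between two surrogate criteria are supported
  (`grader_agreement()`), but reproducing human graders' judgements is out of
  scope.
- Vendor VD algorithms are proprietary; VD here is computed from the en-face
  images by auto-thresholding, so absolute VD values are not comparable to
  device-reported ones, while repeatability structure is.

## A worked example

```{r example, eval = FALSE}
library(octava)

sp <- synthetic_spec(seed = 1) # 516 px, healthy SVP study conditions
st <- generate_stack(sp) # 5 acquisitions + ground truth
reg <- register_stack(st) # similarity + B-spline elastic
avg <- average_stack(reg) # average-intensity projection

d <- diff_pipeline(avg, reg$images[[1]])
d$summary
autoplot(d)

vd <- vessel_density(avg, grid = box_grid())
m <- sapply(
  reg$images,
  function(im) vessel_density(im, grid = box_grid())$per_box[[1]]$vessel_pixels
)
icc(m)
```
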