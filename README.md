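# octava

Registration, averaging and change analysis for OCT angiography (OCTA)
en-face images.

OCTA renders retinal blood flow as en-face images of the capillary plexuses
(superficial plexus, SVP; deep complex, DVC). Single acquisitions are noisy:
background speckle, interrupted vessel walls, bright motion-stripe artifacts.
Averaging five sequential acquisitions suppresses the noise — but does it
only *add* capillary signal, or can it *erase* vessels? And how repeatable
are vessel-density measurements across the five acquisitions in the first
place? `octava` implements the full analysis pipeline for these questions,
for researchers working with repeated en-face angiogram acquisitions:

- **Registration** — each acquisition is aligned to the first with a
  similarity transform `T(p) = s R(θ)(p − c) + c + t` (translation, rotation,
  uniform scale) minimising the mean squared intensity difference under a
  3-level pyramid, then refined with a cubic B-spline deformation field
  (control spacing 32 px) penalised by bending energy
  (`E = mean(r²)/2 + λ‖D²C‖²`, λ = 0.1).
- **Averaging** — per-pixel arithmetic mean over the registered stack
  (average-intensity Z-projection), single rounding to 8-bit.
- **Change analysis** — positive-part difference maps
  `A−S = max(averaged − single, 0)` and `S−A = max(single − averaged, 0)`,
  binarized at slab thresholds (SVP/full 40, DVC 60), red overlays, and
  per-box gain/loss scores on the 3×3 grid of 172×172-px boxes.
- **Vessel density** — VD = vessel pixels / total pixels after Otsu (or
  IsoData) auto-thresholding, whole-image and per box.
- **Repeatability** — ICC(2,1) (two-way random effects, absolute agreement,
  single measurement) across the repeated acquisitions, with F-based 95%
  intervals, stratified summaries, Welch t comparisons, Spearman
  quality-index correlations and binary-grader agreement rates.
- **Synthetic angiograms** — a seeded generator (branching trunks, capillary
  mesh, speckle noise, motion stripes, acquisition jitter, elastic warps,
  intermittent capillary perfusion, cystoid darkening for oedema eyes) with
  full ground truth, so the entire pipeline is testable without patient
  data.

Results come back as tibbles; result objects support `tidy()`, `glance()`
and `autoplot()`.

## A worked example

```r
library(octava)

sp  <- synthetic_spec(seed = 1)   # one healthy SVP eye, 516x516, 5 acquisitions
st  <- generate_stack(sp)         # images + ground truth
reg <- register_stack(st)         # similarity + elastic registration
avg <- average_stack(reg)         # average-intensity projection

d <- diff_pipeline(avg, reg$images[[1]])
d$summary
#> # A tibble: 1 × 6
#>   slab  threshold mean_gain_pixels_per_box mean_loss_pixels_per_box gain_score
#>   <chr>     <int>                    <dbl>                    <dbl>      <int>
#> 1 SVP          40                    2544.                    4005.          9
#> # ℹ 1 more variable: loss_score <int>
```

Every one of the 9 boxes gains capillary signal (`gain_score = 9`): pixels
present in the average but not in the first acquisition, mostly capillaries
that carried no flow signal in that acquisition. The per-box pixel loss is
background noise and motion stripes suppressed by averaging — checked against
ground truth, no consistently perfused vessel is erased:

```r
surrogate_grade_loss(d$loss_mask, st$ground_truth)
#> [1] 0 0 0 0 0 0 0 0 0

m <- sapply(reg$images, function(im)
  vessel_density(im, grid = box_grid())$per_box[[1]]$vessel_pixels)
icc(m)
#> ICC(2,1) = 0.8354  [95% CI 0.4729, 0.9594]  (n = 9 subjects, k = 5)
```

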