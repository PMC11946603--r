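---
title: "Measuring temporomandibular joint space width from ultrasound segmentations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring temporomandibular joint space width from ultrasound segmentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmjjsw)
```

## The measurement problem

Ultrasonography shows the temporomandibular joint (TMJ) as two hyperechoic
(bright) bone-surface bands: the mandibular condyle (MC) below and the
glenoid fossa (GF) of the temporal bone above, separated by the darker joint
space (JS). The vertical width of that gap — the joint space width (JSW) —
is a key morphological parameter: reductions accompany arthrosis and other
degenerative TMJ conditions. Manual ultrasound measurement is operator
dependent, so an automated path is attractive: segment the frame into
MC / JS / GF, clean the predicted mask, and measure the JSW from landmarks
defined on the mask.

`tmjjsw` implements that measurement chain and everything needed to validate
it: mask postprocessing, the landmark measurement rule, segmentation quality
metrics, method-agreement statistics, a synthetic phantom generator with
known ground truth, and a compact residual U-Net training harness for
CPU-scale experiments.

## Data model and conventions

Masks are integer matrices with codes 0 = background, 1 = MC, 2 = JS,
3 = GF, carried by `label_mask()` together with a physical pixel spacing in
mm. Two conventions matter everywhere:

* **Orientation.** Row 1 is the top of the frame. Ultrasound frames render
  superficial/superior structures toward the top, and the fossa is the
  superior joint surface, so *anatomically superior = smaller row index*.
  Any other reading would leave the fossa search region empty in normal
  anatomy.
* **Spacing.** All mm-valued outputs scale pixel distances by the supplied
  spacing. Cropped exported ultrasound frames rarely embed their
  calibration, so spacing is user-supplied metadata (JSON sidecar or
  manifest column), never guessed; images without it default to 1 mm/px
  with a warning.

## Connected-component postprocessing

Predicted masks contain spurious islands. For each non-background class
independently, `filter_components()` labels connected components, takes the
largest as the reference, and keeps a component only if its pixel count is
at least a threshold fraction (default 60%) of the largest; "at least" means
a component exactly at the threshold survives. Three properties follow from
the rule and are enforced by tests: the largest component always survives,
filtering only ever deletes pixels (monotone shrinkage), and the operation
is idempotent.

Two choices were open. *Connectivity*: the adjacency is configurable
(4- or 8-neighbour) and defaults to 8-neighbour, the common default for
2D morphology; the two differ only on diagonal bridges. *Size*: component
"size" is the raw pixel count. With uniform spacing, pixel count and
physical area order components identically, so the simpler notion is used.

## The JSW measurement rule

`measure_jsw()` applies three steps:

1. **Condyle apex** — the MC pixel with the smallest row index. If several
   MC pixels share that row, the median column is taken; with an even number
   of tied columns the lower of the two middle columns is used, which keeps
   the rule deterministic.
2. **Fossa match** — in the apex column, the GF pixel with the largest row
   index strictly smaller than the apex row, i.e. the closest fossa pixel
   directly above the apex. A column without GF reports
   `no_fossa_in_column`; GF only below the apex reports
   `fossa_not_superior` (an `allow_inferior_fossa` flag enables a
   nearest-in-column fallback for pathological predictions).
3. **Distance** — the raw row-index difference between the two landmarks,
   times the row spacing. The convention is the distance *between the
   points*, not the count of gap pixels between them (which would be one
   less), and no sub-pixel boundary interpolation is attempted. The choice
   is documented so users comparing against other conventions can convert.

Anatomical absence is a status, never an exception: downstream code needs to
tabulate failed cases, not crash on them.

## Segmentation metrics

`evaluate_case()` computes, per class, one-vs-rest on pixels:

* Dice $= 2\,TP / (2\,TP + FP + FN)$,
* precision $= TP/(TP+FP)$, recall $= TP/(TP+FN)$,
* volume similarity $VS = 1 - |V_P - V_G| / (V_P + V_G)$ on pixel counts
  (the 2D analogue of a volume comparison; the absolute value keeps
  $VS \le 1$),
* the symmetric Hausdorff distance in mm.

Degenerate classes follow one convention throughout: a class empty in both
masks is vacuously perfect (ratios 1, HD 0); a class present on exactly one
side scores Dice/VS 0 — a completely missed structure is a real failure
worth 0.00, not a missing value — while ratios whose denominator vanishes
(precision with no predicted positives, recall with no reference positives)
and the HD are undefined (`NA`) and are excluded, with a reported exclusion
count, from `summarize_metrics()` aggregation (mean ± sample SD, $n-1$).

The Hausdorff distance uses boundary pixels (foreground pixels 4-adjacent to
non-foreground, image border included) as the point sets, with per-axis
physical spacing: the directed maxima of region-to-region nearest-neighbour
distances are attained on boundaries, and "maximum boundary deviation" is
the quantity of interest. When one overall number is needed,
`overall_dice()` averages the per-class test-set means (classes weighted
equally, not by prevalence).

## Agreement analysis

`agreement_stats()` compares paired AI and reference JSW measurements.
Conventions, chosen once and used everywhere:

* differences are **reference − AI**, so a positive bias means the AI
  under-measures;
* the SD of differences uses the sample ($n-1$) denominator, and the 95%
  limits of agreement are bias ± 1.96 · SD (the classic Bland–Altman
  construction with the normal quantile, not a t-quantile);
* the mean percentage error is the mean of per-case **absolute** errors
  relative to the reference, $\mathrm{mean}(|ai - ref| / ref) \times 100$
  (consequently it is not invariant under swapping the two methods — the
  denominator changes);
* RMSE, MAE and bias obey $\mathrm{rmse}^2 = \mathrm{bias}^2 +
  \frac{n-1}{n}\,\mathrm{sd}^2$, which the tests verify to $10^{-9}$ as an
  internal consistency oracle.

`bland_altman_points()` and `concordance_points()` return plot-ready data;
base-graphics helpers draw the standard two panels.

## The phantom generator

Real annotated TMJ ultrasound is not required for any test: the
`phantom` module generates images whose ground truth is known by
construction. A phantom is two parabolic bone bands — a convex condyle under
a concave fossa — separated by a darker gap of specified width at the apex
column, with class labels painted by the same geometry that renders the
image. The default conditions are a 128 × 128 frame at 0.05 mm/px with true
JSW drawn uniformly from 0.8–4.0 mm: this brackets the clinical range, where
mean joint gaps around 1.9 mm are reported in symptomatic adults and values
a factor of two either side occur in disease. Curvatures, band thickness and
apex position are jittered per sample within feasibility limits checked at
construction.

The geometry guarantees *exact* recovery: the condyle surface's flat tie
region at the apex is symmetric about the apex column (the median-of-ties
rule returns it exactly), and the nearest fossa pixel above the apex sits
exactly `jsw_px` rows higher. `degrade_mask()` adds seeded spurious blobs —
each strictly below the filtering threshold, placed on background with one
pixel of clearance and away from the apex column — so
`filter_components(degrade_mask(m))` reconstructs `m` bit-for-bit; this is
the end-to-end oracle the acceptance tests exercise.

Speckle is modelled as multiplicative Rayleigh-distributed noise
(`image × (1 + s·(R − 1))`, mode-1 Rayleigh) followed by clipping and 8-bit
quantization. That reproduces the granular, signal-proportional texture a
segmentation model sees, but it is a stand-in, not acoustics: there is no
attenuation with depth, reverberation, refraction shadowing or anisotropy,
and mask-space operations never see noise at all (labels are painted
noiselessly). Passing tests therefore demonstrate the correctness of the
measurement chain on masks, and plausibility of the learning harness — not
clinical segmentation performance on patients.

## The residual U-Net harness

The model layer is a from-scratch dense implementation of the 2D residual
U-Net topology: encoder blocks are residual units (first subunit carries the
stride-2 convolution; the shortcut is a strided convolution, or a 1×1
convolution on channel change), a stride-1 bottleneck, and decoder blocks of
a transposed convolution plus a single-subunit residual unit, with skip
concatenation around each deeper level. Subunits are convolution → instance
normalization (affine-free) → dropout → PReLU; the topmost decoder emits
logits through a plain convolution. Convolutions are computed by im2col
gathers and BLAS matrix multiplies; transposed convolutions are implemented
as the exact adjoint of the corresponding strided convolution, so gradients
are exact — the test suite checks backpropagation against central finite
differences to 10⁻⁵ and the parameter count against an independent
closed-form counter.

Unstated details fixed as package choices: intensities are divided by 255;
frames are zero-padded symmetrically to the next multiple of the stride
product (8 for the default three-level configuration) and cropped back after
inference; weights use uniform fan-in initialization and PReLU slopes start
at 0.25; the plateau scheduler defaults to factor 0.5 with patience 10 on
the validation mean Dice; the soft Dice loss (ε = 10⁻⁵ in numerator and
denominator) excludes the background channel by default, both configurable.
Ensembling averages the runs' softmax probability maps before the argmax:
unlike majority voting it degenerates exactly to a single run's prediction
and stays consistent with the training loss. Argmax ties break toward the
lowest class index, deterministically.

"16 residual units per block" makes for an unusually deep encoder; it is
implemented exactly as configured, with the count adjustable. Tests and the
acceptance script run a *toy* configuration — channels 8/16/32, 2 residual
units, 64 × 64 phantoms, 20 training exams, 10 epochs, batch 2, learning
rate 10⁻³ — sized so a full three-run ensemble trains in about a minute on
one CPU while still reaching held-out condyle Dice well above 0.5. Full-size
training on clinical data is supported by the same code path but is not part
of the test suite.

## Splitting protocol

`make_split()` reproduces the 60/15/25 holdout: validation and test sizes
are `fraction × n` rounded half-*down*, the remainder (the larger share)
goes to training — for 142 exams this yields exactly 86/21/35, and for any
`n` the three sets partition the ids and are reproducible from the seed.
Ordinary round-half-even would put 36 exams in a 142-exam test set
(0.25 × 142 = 35.5), which is why the half-down rule is spelled out.

## Numerical notes and limitations

* All component labelling is exact (graph connected components), not
  approximate morphology; tests compare against a breadth-first-search
  oracle.
* The Hausdorff implementation materializes an all-pairs boundary distance
  matrix — fine for single 2D frames, not meant for 3D volumes.
* JSW is measured along image columns only; oblique joint axes, open/closed
  mouth paired analysis and sub-pixel surface localization are out of scope.
* The phantom cohort is the validation substrate. It establishes
  correctness of postprocessing, measurement, metrics and agreement code,
  and that the training harness learns; it cannot establish segmentation
  accuracy on clinical images, which requires the real annotated dataset
  and full-scale training.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
cohort <- generate_cohort(40, jsw_range_mm = c(0.8, 4.0), seed = 11)
ref <- setNames(lapply(cohort, `[[`, "mask"),
                vapply(cohort, function(s) s$mask$id, character(1)))
pred <- lapply(cohort, function(s) {
  degrade_mask(s$mask, n_spurious = 3, seed = s$spec$seed,
               avoid_cols = (s$true_apex$col - 3):(s$true_apex$col + 3))
})
names(pred) <- names(ref)
res <- full_eval(pred, ref)
print(res)
print(res$agreement)
plot_bland_altman(res$pairs)
```
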