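---
title: "Estimating microfossil assemblages from slide scans: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating microfossil assemblages from slide scans: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micrassem)
```

## The problem

The relative abundance of the radiolarian *Cycladophora davisiana* among all
radiolarians (*C. davisiana*%) is a classic stratigraphic signal: it rises in
subarctic sediments during glacial periods and falls during interglacials, so
a down-core *C. davisiana*% curve can be used to correlate and date
carbonate-poor Pleistocene sediments. Producing that curve manually requires
an expert to identify hundreds of specimens per sample under a microscope.
`micrassem` implements the automated alternative: scan the slide, segment
every particle, classify each particle crop into five categories with a
confidence score, and compute assemblage statistics from the classification
records.

The five categories are fixed, in a canonical order used everywhere
(including deterministic tie-breaks):

| code | meaning |
|------|---------|
| `Cdv` | *Cycladophora davisiana*, the target species |
| `Cbc` | *Cycladophora bicornis*, a morphologically similar confusion taxon |
| `Rad` | all other radiolarians |
| `dtm` | centric diatoms |
| `oth` | all other particles (fragments, mineral grains, debris) |

The target statistic uses the radiolarian denominator only:

$$\textit{C. davisiana}\% = \frac{n_{Cdv}}{n_{Cdv} + n_{Cbc} + n_{Rad}} \times 100$$

Diatoms and other particles never enter this ratio; a slide with no
radiolarians has an *undefined* composition (an error), which is distinct
from 0%.

## Segmentation

A scan is a grayscale intensity matrix in $[0,1]$ (dark particles on a light
transmitted-light background) with a physical scale in µm/px. Binarization
applies a contrast gain and brightness offset, then thresholds — Otsu's
histogram criterion in automatic mode, a user threshold in manual mode —
and removes connected regions below `min_region_area_px` (default 20 px) to
suppress noise. Conventions, fixed once and used everywhere:

* **Connectivity is 8-neighbour.** Particles touching only diagonally are one
  object. (The labeling is a 4-connected pass followed by a union-find merge
  of diagonally adjacent labels.)
* **Touching particles are not split.** No watershed: composites are instead
  excluded downstream by the size filter, mirroring how the scanning workflow
  handles overlaps.
* **Coordinates** are 0-based pixels, `x` along columns, `y` along rows, from
  the top-left; bounding boxes are half-open.
* **Crops** are square, 280 px by default (the resolution sufficient to
  characterize radiolarian morphology at the reference optics), centred on
  the region centroid and padded with the modal background intensity when
  they run over the scan edge.
* **Particle size** for the filter is the *equivalent circular diameter*
  $d = 2\sqrt{A/\pi}$ computed from the pixel area; circularity is
  $4\pi A / P^2$, clipped at 1 because rasterized perimeters can slightly
  under-measure. The default scale is 1 µm/px and must be set to match the
  actual optics, which do not determine a unique value.

The size filter defaults to 60–160 µm: smaller objects are commonly out of
focus, larger ones are usually touching composites. On real material roughly
30% of segmented objects fall outside this window; `filter_by_size()` always
reports the excluded fraction.

## Classification

`predict_confidences()` is a pluggable contract: any model that maps a crop
to five scores in $[0,1]$ summing to ~1 (tolerance 0.02, matching tables
printed at two decimals) can serve. The bundled baseline is deliberately
lightweight: crops are resampled bilinearly to 64×64, a morphometric
descriptor is computed (intensity statistics, second-moment eccentricity, a
10-bin radial darkness profile, a 16-bin angular occupancy profile of the
outer zone sorted for rotation invariance, boundary roughness), and a random
forest of 300 trees supplies class-vote confidences. It is deterministic
under its seed and reaches well above 90% held-out argmax accuracy on the
synthetic gallery; it makes no claim to match a production CNN on real
imagery, and whether real classifier confidences are calibrated
probabilities is left open — only the $[0,1]$/sum≈1 behaviour is enforced.

Assignment uses the *strictly-greater-than* rule: an object is assigned to
the argmax category iff its top confidence exceeds the threshold, otherwise
it is `"unclassified"`; ties at the threshold are unclassified, argmax ties
break by canonical category order. The two standard operating points are
0.60 (permissive; most objects assigned, lower precision) and 0.95 (strict;
roughly half of real-slide objects are retained but the target-species
precision is high). The assigned count is non-increasing in the threshold —
a property the tests sweep.

Training galleries are augmented by lossless right-angle rotations (90°,
180°, 270° by default; arbitrary angles would interpolate and are rejected)
plus, optionally, Gaussian-blur copies of a seeded random fraction to
emulate imaging without focus stacking.

## Assemblage statistics

* `tally()` — per-category counts plus unclassified; counts always sum to
  the record total.
* `relative_abundance()` — the count-based formula above, on one tally.
* `averaged_confidence_composition()` — the threshold-free alternative: mean
  confidence per category over *all* records, then the same ratio on the
  means. No object is excluded, at the cost of having no per-object accuracy
  guarantee. For the bundled reference slide (#37) the published category
  means (0.16, 0.02, 0.44) give 25.8%; the expert count on the same sample
  was 28.2%.
* `evaluate_accuracy()` / `aggregate_reports()` — per-category precision
  (share of objects assigned to a category whose true label is that
  category) and unclassified percentage, aggregated across slides with the
  arithmetic mean and the *population* standard deviation (divisor $n$ —
  the convention pinned by the bundled benchmark tables). A category with
  zero detections has *undefined* (NA) precision, never a silent 0%, and is
  dropped from that category's aggregation.
* `fit_calibration()` / `apply_calibration()` — ordinary least squares of
  manual-count abundance on model abundance with Pearson's $r$. The
  regression runs in this direction because the calibration maps model
  output onto actual count data (a slope above 1 reads as model
  underestimation, as observed when the other-radiolarian category is
  detected less completely than the target species). Calibrated values are
  clipped to $[0,100]$.

Reported percentages are conventionally rounded to one decimal place;
computation is at full precision throughout.

The package ships the published per-slide benchmark reports of the two
reference CNN models (Cdv%v2 and Cdv%v6R, trained on 2 MP and 5 MP imagery)
on Southern Ocean core DCR-1PC test slides (`reference_reports()`), plus the
slide #37 worked confidence example (`reference_slide37()`). These are
*evaluation outputs*, usable as inputs to the aggregation and composition
functions; the underlying images are not deposited anywhere, so per-object
recomputation of those tables is not possible. In particular the published
full-precision averaged-confidence value for slide #37 (26.1% over 500
objects) cannot be recomputed from the rounded means; the package asserts
the 25.8% value the rounded means imply.

## Synthetic data: what it emulates and what it does not

Because no imagery is deposited, the test bed is synthetic and fully
seeded.

**Slides.** `generate_slide()` renders each category as a distinct
parametric silhouette: a latticed ellipse (Cdv), a horned ellipse (Cbc), a
spined circle (Rad), a concentric-ring disc joined by radial spokes (dtm),
and an irregular harmonic blob (oth). Diameters are lognormal (positive and
right-skewed, as sieved particle populations are; default median 100 µm,
log-sigma 0.12, inside the 60–160 µm window at the default 1 µm/px scale).
Placement is uniform with rejection sampling so silhouettes never touch
(bounded retries, then a packing error); a seeded fraction (default 0.2) is
defocus-blurred; Gaussian pixel noise (sd 0.02) is added. The ground-truth
centroid recorded per particle is the rendered silhouette's own pixel
centroid — exactly what a faithful segmentation should recover. The default
field is 1600×1200 px with 50 particles, a desk-scale stand-in for a real
scan's thousands of objects.

These silhouettes are caricatures built for separability, not radiolarian
anatomy. A classifier that is perfect here says nothing quantitative about
real imagery — that is what the bundled benchmark reports are for. What the
synthetic slides *do* establish is the correctness of the plumbing:
segmentation recovers exactly the planted count with sub-2-px centroids, and
the classifier/composition machinery behaves as specified.

**Confidence tables.** `generate_confidence_table()` draws each object's
true label from a specified composition and its confidence vector from a
Dirichlet centred on the true label: mean mass $1-\delta$ on the truth plus
$\delta/5$ everywhere (default $\delta = 0.02$), total concentration
$\kappa$ as the single sharpness knob (the spec of each experiment states
its $\kappa$; 50 gives crisp, mostly-assignable vectors). Dirichlet is the
minimal simplex-valued family matching the printed confidence structure;
vectors sum to 1 exactly. One known limitation: a single-$\kappa$ Dirichlet
is unimodal in sharpness, so it cannot reproduce the strongly bimodal
assigned-fraction pattern of real slides (about 90% assigned at threshold
0.60 *and* only about 50% at 0.95); the monotonicity of assignment in the
threshold is asserted instead, which is the property that matters for the
estimators.

**Estimator recovery.** With composition set so radiolarians hold ~62% of
objects (as on the reference slide) and the true Cdv share within
radiolarians at 5/15/25%, both estimators recover the truth within three
binomial standard errors at $n = 2000$, $\kappa = 50$ — the package's
stand-in for the agreement with expert counts that cannot be reproduced
without the original slides.

## Numerical choices and degenerate inputs

* Otsu on a constant image is undefined; a constant scan yields an empty
  mask (no particles), not an error.
* A manual threshold outside the image's intensity range simply yields an
  empty (or full) mask; only a non-positive contrast gain is an error.
* Crop padding uses the modal background intensity (mode of the 255-level
  histogram of background pixels).
* Gaussian-blur sigma is clamped so the filter brush fits small images.
* Dirichlet draws with all-zero gamma variates (possible only at extreme
  parameters) fall back to a one-hot vector on the true label.
* `fit_calibration()` refuses a constant predictor (degenerate OLS), and
  composition functions refuse zero radiolarian denominators.
* Problem sizes in the test suite are desk-scale by design: 1600×1200
  synthetic scans with 50 particles, galleries of 40–60 crops per category,
  confidence tables of 1000–2000 rows. The full suite runs in well under a
  minute on one CPU.

## Reproducibility

Every stochastic component (slide generation, gallery synthesis, Dirichlet
tables, training, augmentation sampling) is deterministic under an explicit
integer seed, and reruns of `run_pipeline()` with identical configuration
and inputs produce byte-identical CSVs. `scripts/acceptance.R` recomputes
the package's headline quantities from scratch; see the README for how to
run it.
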