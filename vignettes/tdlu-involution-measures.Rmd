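---
title: "Measuring TDLU involution: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring TDLU involution: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdlumetry)
```

## The measurement model

Terminal duct lobular unit (TDLU) involution is scored from three
ingredients observed on a slide: a tissue-foreground mask, an adipose
estimate, TDLU instances, and acini point detections. `tdlumetry` treats
the detector/segmenter as a pluggable *backend* and owns everything
downstream: the integration of those observations into five quantitative
and two qualitative involution measures, and the agreement statistics used
to validate them against human observers.

All coordinates are 0-based `(x, y)` with `y` downward and points at pixel
centres; rasters are indexed `(row = y + 1, col = x + 1)`. One stated
convention, used everywhere, avoids off-by-one ambiguity between the
raster and point worlds.

### Adipose-adjusted tissue area

Breast tissue rich in adipose carries few TDLUs, so densities are
expressed per unit of *non-adipose* tissue:
\[ A_\mathrm{adj} = A_\mathrm{tissue}\,(1 - f_\mathrm{adipose}). \]
`f_adipose` comes either from a mask (automated path: the adipose∧tissue
pixel fraction) or from an observer's categorical estimate, in which case
the bin centres (12.5, 37.5, 62.5, 87.5 per cent) stand in for the bin.
Both reduce to one number, so manual- and automated-arm measures are
directly comparable.

### Span from second central moments

A pathologist measures span by picking the two most distant boundary
points; the automated definition is the length of the major axis of the
ellipse with the same normalized second central moments as the region:
\[ \mathrm{span} = 4\sqrt{\lambda_{\max}(\Sigma)} \times \mathrm{res}, \]
with \(\Sigma\) the population covariance of the instance's pixel-centre
coordinates. For a filled disc of radius \(r\) the variance along any axis
is \(r^2/4\), so the span equals the diameter; for an ellipse with
semi-axes \(a \ge b\) it equals \(2a\) regardless of orientation. We apply
no pixel-extent variance correction (the uniform-pixel +1/12 term): for
regions tens of pixels across the difference is below one pixel, and the
uncorrected form matches the moment-ellipse convention used by standard
region-properties implementations. The tests exercise discs and rotated
ellipses against these closed forms at a 2 % rasterization tolerance.

### Acini per TDLU and calibration

Each acinus detection is assigned to the TDLU instance whose pixels
contain its centroid — no nearest-instance snapping, which keeps the rule
faithful to "a TDLU is a cluster of acini" and makes assignment
deterministic. Automated acini counts undercount relative to a human
(a detector marks one point per resolved acinus profile), so the median
acini/TDLU is mapped onto the manual counting scale by a multiplicative
calibration, default coefficient 3.888, fitted by least-squares regression
through the origin of manual on automated counts. The free-intercept fit
is always computed alongside and its intercept estimate and standard error
are reported, documenting whether the origin constraint is tenable.
Because calibration is linear and the median is order-preserving,
calibrating the median equals the median of calibrated counts; a test
asserts this identity exactly.

The other four measures are never calibrated: `acini_per_mm2` uses raw
detections (it is defined per tissue area, not per TDLU, and the
calibration was derived for the per-TDLU measure only), and counts, spans
and areas are direct geometry.

### Qualitative classification

Russo lobule types use the historical acini-count thresholds: type 1
below 12, type 2 from 12 to 80, type 3 above 80. Two conventions had to be
fixed where the verbal definitions are ambiguous:

* counts are taken on the *calibrated* scale by default (the thresholds
  were defined for manual counting; `useCalibrated = FALSE` switches to
  raw counts);
* the boundary value exactly 80 is assigned to type 2, reading
  "between 12 and 80" inclusively.

The slide's predominant type is the modal type, with ties broken toward
the **higher** (less involuted) type — deterministic, and conservative in
the sense of flagging less involution; it is configurable by reordering
the input if a different convention is wanted. Baer categories follow the
three-way rule: *no type 1*; *predominantly type 1 and no type 3*
("predominantly" read as a strict majority, the weakest reading consistent
with the word); *mixed* otherwise. Slides without TDLUs get undefined
(NA) qualitative results rather than a default category. Multi-rater
consensus is strict-majority voting, returning NA (for adjudication) when
no strict majority exists.

## Agreement statistics

Detection quality is scored by one-to-one matching between predicted and
true points: maximum-cardinality bipartite matching over all pairs within
the match radius. The radius is a genuinely free parameter of the
evaluation — published validations of this design rarely state their hit
criterion — so it is explicit everywhere, defaults to 15 μm (the order of
an acinus radius), and is recorded in evaluation output. Precision,
recall and F1 use the standard definitions (precision = positive
predictive value, recall = sensitivity). Dice is computed from the same
formula on pixel sets, so `dice(a, b)` and pixel-set F1 coincide exactly —
a property the tests assert rather than assume. Two empty masks score
Dice 1 (perfect agreement on absence).

ICC(3,1) — two-way mixed effects, consistency, single rater — is computed
from the subjects × raters ANOVA decomposition
\[ \mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E}, \]
with 95 % confidence bounds from the F-distribution mapped through
\((F-1)/(F+k-1)\). Consistency ICC is invariant to per-rater additive
offsets and common affine rescaling; both invariances are tested, and the
statistic is checked against an independent `aov()`-based oracle on
randomized tables. Fleiss' κ follows the standard formulation from the
subjects × categories count table, with the large-sample \(z =
\kappa/SE_0\) test against κ = 0; it is checked against a direct formula
oracle. Intra-observer designs (one observer, two sessions) reuse the
same computation with `nRaters = 2`; κ then measures session consistency,
not inter-rater agreement, which the analyst should keep in mind when
comparing values across designs.

Association tests (Spearman, Mann–Whitney U, Kruskal–Wallis, χ²) are thin
wrappers over the base-R implementations — they are standard tools, not
this package's contribution.

## The synthetic slide generator

Real validation cohorts of benign-biopsy whole-slide images are not
publicly available, so the test harness is a generator with exact ground
truth. A slide is a tissue region (inset rectangle or perturbed ellipse)
containing `nTdlus` non-overlapping TDLU discs, each filled with a drawn
number of non-overlapping annular acini (lumen + epithelial ring — the
"small spherical structures lined by epithelial cells" that a detector
keys on), plus adipose blobs added until the raster adipose fraction
approximates the target within ±0.05. The render uses a fixed pseudo-H&E
palette: white background, pink extra-lobular stroma, lavender
intra-lobular stroma, near-white adipose, purple epithelium.

Default conditions were chosen once to emulate realistic magnitudes and
are not tuned per test: 2048 × 2048 px at 2 μm/px (≈ 16.8 mm²; a
downsampled working magnification — full 0.16 μm/px scans are gigapixel
and add nothing to the method's logic), 8 TDLUs (≈ 0.7/mm² adjusted),
TDLU radii 150–400 μm (spans 300–800 μm), lognormal acini counts with
median 15 truncated to [1, 120], acinus radii 12–20 μm, adipose target
0.30. Two generator-internal guards keep requested geometry feasible: a
drawn TDLU radius is enlarged when its drawn acinus count cannot pack into
the disc (random sequential placement jams near 40 % area density), and
adipose blob radii are capped at ~2.5 % of tissue area per blob so the
fraction guarantee holds on small frames. Infeasible requests (TDLU area
exceeding half the tissue, or a radius exceeding the tissue extent) raise
errors rather than degrade silently.

Ground-truth measures come from the planted geometry: counts are the
planted draws, spans the planted diameters, and areas the rasterized
instance areas, so span and area are raster-consistent within the 2 %
rasterization tolerance while counts and densities are exact.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: stain and texture variability, out-of-focus and
scanning artifacts, TDLUs with irregular (non-disc) outlines or complex
mutual clustering, proliferative/metaplastic epithelium (which real
pipelines must exclude), dilated acini, and boundary ambiguity between
intra- and extra-lobular stroma. Results on synthetic slides certify the
*measurement and statistics machinery*, not any segmentation model's
histology performance.

The observer simulator mirrors the manual protocol used in validation
studies: a random ROI of ≈ 50 mm² (clipped to the slide), TDLU counting in
the ROI, subsampling of up to 10 TDLUs for span/acini reads, a binned
adipose estimate, optional multiplicative reading noise, and an optional
hidden counting-scale factor — the piece that lets calibration fitting and
ICC behaviour be studied with known truth.

## Segmentation backends

The *reference* backend inverts the renderer: nearest-palette-colour
classification, tissue = non-background, adipose = adipose colour, the
TDLU semantic mask = intralobular stroma ∪ rings ∪ lumina (instances via
4-connected components), and acini = centroids of ring components filtered
on size (8–8000 px) and annularity (component fills at most 92 % of its
bounding disc — a solid blob fills ≈ 100 %). It is a deterministic test
double tuned to the synthetic palette, documented as such, and not a
histology segmenter.

The *trainable* backend is a random-forest pixel classifier on RGB plus
5×5 and 11×11 local channel means, trained per task from labelled patches
with seeded subsampling. It demonstrates the full train → integrate →
measure loop at desk scale; tests require it to exceed Dice 0.8 on
held-out synthetic adipose patches. Patch-wise execution uses
central-crop stitching (`tileAndStitch`): with overlap *o*, any per-pixel
function needing at most *o*/2 of spatial context produces output
identical to untiled execution, which the tests verify. Per-slide
cross-validation splitting (`cvFolds`, e.g. 5- or 9-fold) is provided as a
pure seeded function.

## Numerical choices and degenerate inputs

* Medians: even-length inputs use the mean of the two central order
  statistics (R's default); slides with no TDLUs report NA medians with a
  warning, and zero densities.
* Zero adjusted area (no tissue, or 100 % adipose) is an error — densities
  are undefined, and silently returning 0 would fake complete involution.
* `minTdluAreaMm2` (default 0 = no filter) excludes instances *before*
  all statistics, so a size filter changes every downstream measure
  consistently.
* Polygon rasterization uses the even-odd rule with parity evaluated just
  above and below each scanline, making boundary pixel centres inclusive;
  a 10 × 10 px square annotation fills exactly 100 pixels.
* Label masks round-trip as 16-bit single-channel TIFF (dense slides can
  exceed 255 instances); readers reject multi-channel images and malformed
  schemas rather than coerce.
* ICC with zero residual variance returns 1 with a degenerate (1, 1)
  interval; zero total variance is an error. Fleiss' κ with all mass in
  one category is an error (chance agreement is 1, κ undefined).
* Matching is deterministic under input permutation; cardinality is
  optimal, so F1 is permutation-invariant and symmetric under swapping
  prediction and truth (with precision and recall exchanged).

## Problem sizes

The shipped tests run the full-size default slide (2048², the end-to-end
smoke test and the acceptance script's main computation) once, and
otherwise use scaled specs — 768² slides with 80–180 μm TDLUs for
multi-slide recovery and observer studies, 384² patches for backend
training, 2 160 planted acini for the detection operating-point study,
1 000 random 5 × 3 tables for the ICC oracle — sizes chosen so the whole
suite exercises every property in about a minute while keeping sampling
error well inside the asserted tolerances.

## Known limitations

* The measures operate on whatever observations a backend supplies;
  garbage segmentation yields garbage measures, and only the reference
  backend (on synthetic renders) is validated here.
* The tissue mask is an input; the package does not compute tissue
  foreground from RGB.
* Acini are represented as centroids; extent-based acinus statistics are
  out of scope.
* Type 4 (pregnancy/lactation) lobules are not modelled; slides from
  pregnant or lactating women are outside the method's domain.
* The calibration model is a single multiplicative factor; if the
  automated/manual relationship were nonlinear or slide-dependent, the
  through-origin fit would average over it. The reported free-intercept
  diagnostic is the first check against that.
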