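---
title: "Measuring the fetal PA/Ao ratio from segmentation masks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the fetal PA/Ao ratio from segmentation masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caliper3vv)
```

## The problem

In fetal cardiac ultrasound screening, the three-vessel view (3VV) shows the
pulmonary artery (PA), ascending aorta (Ao) and superior vena cava (SVC) in
cross-section. The ratio of PA to Ao diameter is a screening biometric for
congenital heart disease (CHD): pulmonary stenosis (as in tetralogy of
Fallot) pushes it low, aortic narrowing (coarctation) pushes it high, and in
normal fetuses it sits around 1.1–1.4. Measured by hand it suffers from
intra- and inter-observer variability; `caliper3vv` implements the automated
measurement chain that starts from a per-pixel vascular segmentation of the
3VV and ends in a screening decision, together with the evaluation machinery
(Dice, ROC/AUC) and a synthetic phantom generator that makes every stage
testable with known ground truth.

The package deliberately stops at the segmentation mask: producing masks (by
a neural segmentation model or by manual annotation) and extracting 3VV
frames with an object detector are upstream concerns. Their *outputs* — label
masks and detection text files — are this package's inputs.

## The diameter definition

A vessel's cross-section in a label mask is a pixel region $D$ (we take the
largest 8-connected component of its class). Its **long axis** is the
principal eigenvector of the covariance of the pixel coordinates — the
PCA direction of the region. The **diameter** is the longest chord
perpendicular to that axis:

$$
\mathrm{PA},\ \mathrm{Ao} \;=\;
\max_{\substack{a, b \in D,\ a \ne b \\ \overline{ab} \perp \ell}}
\lVert a - b \rVert ,
$$

where $\ell$ is the long axis. On a discrete lattice "perpendicular" means
the projection of $a - b$ onto the axis direction is at most `tol_px`
(default 0.5, half the pixel-center spacing). Two implementations are
provided and kept contractually identical: `perpendicular_diameter()`, a
sorted-projection sweep that only enumerates pixel pairs inside the
tolerance band, and `diameter_oracle()`, the literal all-pairs enumeration
retained as the reference. The test suite asserts their exact agreement on
hundreds of random blobs.

```{r}
mask <- generate_phantom_frame(
  pa = ellipse_spec(c(30, 25), a = 16, b = 12, theta = 20, class_code = 1),
  ao = ellipse_spec(c(30, 70), a = 14, b = 10, theta = 100, class_code = 2),
  canvas = c(61, 101))$mask
measure_frame(mask)
```

Choices a user should know about:

* **Long axis by PCA.** The long axis of an approximately elliptical region
  is not otherwise well defined on a raster. For near-circular regions the
  PCA direction is unstable, so `principal_axis()` reports the eigenvalue
  ratio (`anisotropy`) and flags regions with anisotropy < 1.05; the
  diameter itself is rotation-insensitive there, so measurement proceeds.
* **Perpendicular to the long axis.** For an ellipse this returns the full
  minor axis ($2b$), which is the intended vessel caliber; the chord through
  the region's widest perpendicular extent is what a sonographer's caliper
  line approximates.
* **Center-to-center lengths.** `length_px` is the Euclidean distance
  between the extreme pixel *centers*. The alternative pixel-extent
  convention (add 1 px) is available via `extent_correction = TRUE`; the
  difference cancels in the PA/Ao ratio, which is why the default stays off.
  Note that center-to-center lengths are not perfectly extensive: upscaling
  a mask by an integer factor $k$ adds up to $k-1$ px of pixel extent, while
  extent-corrected lengths scale cleanly — the covariance test in the suite
  uses the corrected convention for exactly that reason.
* **Ties.** Equal-size components are broken by the topmost-then-leftmost
  anchor; equal-length chords by the canonical pixel ordering. All results
  are deterministic.

## Ratio, standard value and grouping

`compute_ratio()` forms PA/Ao; `clip_ratio()` caps outliers at 3.5 (capping
precedes both standard-range estimation and classification). The **standard
value** is the cohort mean with a ±2 SD band; `compute_standard_range()`
estimates it with the sample SD ($n-1$ denominator — the customary unbiased
choice for a cohort estimate), and `default_standard_range()` carries the
bundled reference value $1.237 \pm 0.364$ derived from 270 normal fetuses.
Classification is inclusive at the boundaries: a ratio exactly at
mean ± 2 SD is *normal*; below/above the band is *low*/*high*. For a
normally distributed cohort the band excludes ≈ 4.55 % of its own mass, a
property the suite checks on $10^5$ draws.

```{r}
sr <- default_standard_range()
sr
classify_ratio(c(0.80, 1.30, 1.70), sr)
```

## Screening evaluation

The screening score of a case is the absolute deviation of its capped ratio
from the standard-value mean, $|r - \bar{r}|$, so low and high abnormalities
both score high. `roc_auc()` sweeps thresholds over the unique scores
(descending, ties grouped), with CHD as the positive class; its trapezoidal
AUC equals the Mann–Whitney pair statistic with ties counted ½, an identity
the suite verifies to $10^{-9}$ and cross-checks against pROC.
`rater_evaluation()` applies the same scoring to per-rater manual
measurement tables and averages AUCs within skill groups (per-rater-then-
mean, matching "arithmetic means of the AUCs").

Segmentation quality uses the Dice coefficient
$2\,TP / (2\,TP + FP + FN)$ per class and its per-frame mean (mDice).
A class absent from both masks has an undefined (0/0) Dice; the default
excludes it from the mean, and `absent_value = 1` switches to the
"perfect agreement on absence" convention.

## Augmentation

Training-set augmentation combines a bounded rotation (uniform on ±15°) with
the 8-bit linear intensity transform
$\mathrm{dst}(I) = \mathrm{saturate\_cast}(\mathrm{src}(I)\,\alpha + \beta)$,
$\alpha \sim U(0.7, 1.3)$, $\beta \sim U(-30, 30)$. `augment_set()` returns
the originals plus 20 variants per image by default — a 21-fold expansion.
Details fixed here because the transform alone does not determine them:

* `saturate_cast()` rounds half away from zero before clamping to
  $[0, 255]$, so $(\alpha, \beta) = (1, 0)$ at angle 0 is a bit-exact
  identity.
* Rotation is about the canvas center with the canvas size preserved and
  background fill 0; bilinear interpolation for images,
  nearest-neighbor for masks (the class alphabet survives exactly). Paired
  image/mask augmentation shares the drawn angle.
* A ±15° round trip recovers a smooth, centrally supported image to well
  under 3 intensity levels of mean absolute error. That bound is a property
  of *smooth* content: bilinear interpolation acts as a low-pass filter, so
  on raw white noise the round-trip error is dominated by the noise itself,
  and content touching the canvas corners is clipped. The test fixture is
  therefore a seeded smooth ultrasound-like image (Gaussian bumps inside a
  centered disk on black background) — which is also the geometry of a real
  ultrasound fan.

## Frame selection

For video screening, per-frame detector output (YOLO text dialect) is
filtered by the study's operating point: a frame is a 3VV candidate iff PA,
Ao and SVC each have at least one box at confidence ≥ 0.001, 0.1 and 0.01
respectively ("detected simultaneously" is read as *all three pass*, with
any-box semantics per class), and up to two frames per video are drawn
uniformly without replacement, seeded. The very low PA threshold mirrors the
upstream detector's weak PA confidence; all thresholds are configuration.

## The phantom generator

`generate_phantom_frame()` rasterizes elliptical vessel cross-sections with
pixel-center-inside membership (no anti-aliasing), so pixel counts are exact
and reproducible — a circle of radius 10 contains exactly 317 lattice
points. An ellipse with semi-minor axis $b$ has ground-truth perpendicular
diameter $2b$, giving every downstream measurement a known answer.

`generate_cohort()` draws true ratios per case — normal cases from
$N(1.237, 0.182)$ (the SD chosen so the ±2 SD band reproduces the bundled
standard value), CHD cases from a three-component mixture with weights
0.3/0.4/0.3, means 0.9/1.25/1.65 and SD 0.15 — and realizes each ratio as an
ellipse pair with the Ao minor full-axis fixed at 30 px and the PA's scaled
by the ratio. The mixture is a fixture choice patterned loosely on reported
group statistics, *not* measured clinical values; its middle component
deliberately leaves many CHD cases inside the normal band, which is also the
clinically realistic situation.

Numerical sizing: with the center-to-center convention each measured
diameter loses up to ~1 px of pixel extent, so at a 30 px Ao base the
systematic slope of measured on true ratio is about 1.03 — inside the
1 ± 0.05 recovery band the tests enforce — and the per-case error stays
under ±0.1. A much smaller base diameter would push the bias out of that
band, which is why 30 px is the default.

What the phantoms do *not* emulate: speckle texture, shadowing, blurred or
broken vessel boundaries, neighboring structures that confuse segmentation,
and the 3VTV/4CV plane-confusion failure mode of frame selection. Passing
the phantom-based tests therefore demonstrates that the *measurement chain*
is correct on clean masks of known geometry; it says nothing about
segmentation quality on clinical images, which must be established upstream.

`degrade_mask()` (per-class erosion/dilation, rigid shift, pixel dropout)
provides controlled departures from a perfect mask for studying how
segmentation error propagates into Dice values and ratios.

## Screening recovery on synthetic cohorts

On the default 1000-case cohort the measured-ratio deviation score yields an
AUC of about 0.75: the 0.4-weight CHD component centered at 1.25 is inside
the normal band by construction, which caps attainable discrimination near
$0.3 + 0.7 \times 0.87 \approx 0.7$. Restricting CHD cases to the separable
low/high groups raises the AUC to about 0.88, and a cohort whose "CHD"
distribution is identical to the normal one sits at chance (0.5), confirming
the score carries no spurious signal. These are properties of the chosen
fixture distributions, not clinical performance claims; the acceptance
script recomputes all three numbers.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use 200 random blobs of 5–2000
pixels for the sweep-vs-oracle equivalence, 100 ellipses and 100 phantom
frames for recovery, $10^5$ draws for band coverage, and two 1000-case
cohorts for screening recovery — sizes at which every Monte-Carlo margin in
the assertions is comfortably wide while a full run stays in the minutes
range on a single core.

## Known limitations

* Diameters are in pixels and the package never calibrates to millimeters;
  only the dimensionless ratio is clinically interpreted.
* One vessel per class per frame: multiple same-class components are
  resolved by keeping the largest, which is the right behavior for spurious
  islands but will silently pick one vessel if a mask truly contains two.
* The PCA long axis degrades gracefully but arbitrarily for near-circular
  regions; the `near_degenerate` flag is the hook for callers that want to
  treat those differently.
* Label masks travel as 8-bit grayscale PNGs whose pixel value is the class
  code (0–3); color or palette PNGs from other tools need remapping through
  `read_label_mask(remap = ...)` or conversion upstream.
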