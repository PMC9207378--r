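---
title: "Quantifying late-expiratory flattening of the flow-volume loop"
author: "fvlSAD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying late-expiratory flattening of the flow-volume loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fvlSAD)
```

## The problem

Small airways (peripheral airways under 2 mm internal diameter) contribute
little to total airway resistance, so their disease does not depress
FEV1/FVC. What it does change is the shape of the expiratory limb of the
flow-volume loop (FVL): premature closure of small airways makes the late
expiratory portion of the curve abnormally flat. In practice that
"flattening" is judged by eye, with considerable inter-rater disagreement.
`fvlSAD` makes the judgement quantitative, in two stages:

1. **Digitization.** Clinical pulmonary function test (PFT) reports are
   usually available only as rendered pages. The package locates the FVL
   panel on a raster page, calibrates its axes, and traces the expiratory
   limb back into (volume, flow) samples.
2. **Index computation.** The traced (or directly supplied) limb is reduced
   to three landmarks and two fitted line segments, from which three
   flattening indices are computed.

## Landmarks and indices

On an expiratory limb with volume $v$ (L, increasing from the start of
expiration) and flow $\dot V$ (L/s):

* **A** — the sample of peak expiratory flow (first sample on ties);
* **B** — the point reached after 75 % of the expiratory vital capacity
  (the FEF75 locus), with flow linearly interpolated between the bracketing
  samples;
* **C** — the end of the limb, on the volume axis; $FVC = v_C$.

Ordinary least squares lines are fitted to the A–B and B–C spans (the
interpolated B is included in both). Writing $s_{AB}, s_{BC}$ for the two
slopes and $a$ for the x:y aspect (flow units drawn per volume unit,
default 1), the indices are

* $\angle ABC = 180^\circ - (\theta_{AB} - \theta_{BC})$ with
  $\theta = \arctan(|s|/a)$ — the interior angle at B between the two
  fitted lines. A flat tail gives a small $\theta_{BC}$ and hence a more
  acute angle; collinear descent gives exactly $180^\circ$.
* $\angle BCX = \arctan(|s_{BC}|/a)$ — the inclination of the late segment
  against the volume axis.
* $\log(BC/A\!-\!x) = \log_{10}(|s_{BC}| / PEF)$ — the late-segment slope
  normalized by peak expiratory flow (the vertical distance from A to the
  volume axis). The normalization compensates for report axes that are
  auto-scaled to the data; the log makes the right-skewed ratio
  approximately Gaussian.

```{r indices}
out <- generateCurve(curveSpec(fvc = 4, vPeak = 0.5,
                               thetaAb = 60, thetaBc = 40))
computeIndices(out$curve)
```

### The aspect parameter

Angles are not invariant to rescaling one axis. Reports draw the loop at
whatever aspect their layout dictates, and nothing in a digitized curve
says which aspect a human eye judged it at. The package therefore computes
angles in value space at a fixed, explicit aspect (`aspect = 1`, i.e.
1 L/s per L), and exposes the parameter so pixel-space behaviour can be
reproduced by passing the panel's own pixel aspect. Both angle indices are
invariant to multiplying all flows and the aspect by a common factor,
which is what makes a fixed-aspect convention meaningful across reports.
The log-ratio index is invariant to rescaling the flow axis (slope and
peak flow scale together); rescaling the volume axis shifts it by a
constant, which affects no comparison made at a common FVC convention.

### Boundary and degeneracy rules

* Peak-flow ties resolve to the first sample at the maximum.
* A curve whose peak lies at or beyond 75 % of FVC has no A–B descent and
  raises a degenerate-curve error.
* A zero B–C slope makes the log ratio undefined; this is an error, not
  $-\infty$.
* End-of-curve tolerance: the final sample must lie within 0.05 L/s of the
  volume axis, and flows may dip 0.05 L/s below zero (tracing noise).
* Classification at a cutoff is strict: flattening iff index < cutoff.

## Digitization

**Panel localization.** The panel is found by its printed locator label.
The label raster is reduced to a 64-bit average hash (8×8 block means
thresholded at their mean; ties map to 1, so a constant raster hashes to
all ones) and every window of the label's size on the page is scored by
Hamming distance, computed for all positions at once with an integral
image. The minimum-distance window wins (ties: leftmost column, then
topmost row); a window is only accepted within a Hamming threshold
(default 4 of 64 bits), otherwise a panel-not-found error reports the best
distance seen. The search is page-global; a region restriction is possible
by cropping the page first.

**Axis calibration.** The axis origin is taken as the intersection of the
longest horizontal and longest vertical dark runs inside the panel — on a
report panel those are the axis lines themselves. A digit glyph (the
number 2 in the bundled layout) is then hash-searched in the band below
the volume axis and the band left of the flow axis. Each match, displaced
by the digit's tick offset, contributes a (pixel, value) pair; with the
origin pinned at value 0 the affine map of each axis is fitted by least
squares, so a single digit per axis suffices and several matches are used
jointly. Calibration fails loudly, naming the axis, when the digit is
absent.

**Tracing.** After masking the calibrated axis row and column, ink is
separated from background by a global intensity threshold (default 128 of
255). In each pixel column the topmost contiguous ink band above the
volume axis — the expiratory limb always lies above the inspiratory limb —
is reduced to its centroid row. Samples are mapped to value space and are
volume-ordered and unique by construction. Because the final stroke of a
curve sits about one stroke-width above the axis line, the trace ends a
pixel short of zero flow; the axis crossing is appended by extrapolating
an OLS fit of the last five samples (capped at 0.75 L), so landmark C lies
on the axis. Fewer than 10 traceable columns is a trace failure.

Input pages are PNG or TIFF rasters. PDF reports should be rasterized to
one of those formats upstream (around 200 dpi works well); page geometry
is resolution-independent because all calibration is per-page.

## Cohort statistics

`summarizeCohort()` derives the classification cutoff the way the index
was validated clinically: the mean minus $k$ standard deviations (sample
SD, $n-1$ denominator; default $k = 1$) of a reference group judged
non-flattening by an expert. With the published reference moments
(163.8 ± 14.1°) this gives the 149.7° cutoff. It also reports a parametric
lower limit of normal, mean $- z_{0.95}\,SD$ with $z_{0.95} = 1.6449$, and
the interpolated empirical percentile. `concordanceRate()` is agreement
counting (matches over total); `fleissKappa()` implements the standard
multi-rater chance-corrected agreement with Fleiss' large-sample standard
error for the normal-approximation CI (no installed package provides it,
so it is implemented here and cross-checked in the tests against a direct
expansion of the agreement definitions). A subject-resampling bootstrap CI
is available behind a seeded flag. An all-one-category panel has expected
agreement 1; kappa is returned as 1 with a degenerate CI and a warning
rather than 0/0. `twoSampleT()` is a thin wrapper over the classical
equal-variance unpaired t-test for group-comparison reports.

```{r cohort}
refVals <- 163.8 + c(-1, 1) * 14.1 / sqrt(2)  # mean 163.8, sample SD 14.1
summarizeCohort(refVals, k = 1)
```

## What the synthetic fixtures emulate

`curveSpec()`/`generateCurve()` produce expiratory limbs with known ground
truth. The piecewise-linear shape is a straight rise to the peak followed
by two exact descent segments at requested inclinations
$\theta_{AB}, \theta_{BC}$, with B at 75 % of FVC and C at (FVC, 0). That
construction is deliberately over-determined: once FVC, the peak volume
and the two inclinations are chosen, the peak flow is implied
($PEF = 0.25\,FVC\tan\theta_{BC} + \tan\theta_{AB}(0.75\,FVC - v_{peak})$),
so `pef` defaults to the implied value and a contradictory explicit value
is an invalid-spec error. Ground truth is closed-form:
$\angle ABC = 180 - (\theta_{AB} - \theta_{BC})$, $\angle BCX =
\theta_{BC}$, $\log_{10}(\tan\theta_{BC}/PEF)$. The smooth-power shape,
$\dot V = PEF\,((FVC - v)/(FVC - v_{peak}))^\gamma$, has no closed form;
its truth is the index chain evaluated on a dense noise-free sampling.
Noise is additive Gaussian on flow only (seeded; endpoints kept exact and
flows clamped at zero).

`renderReport()` draws a curve into a report-like page — axes, integer
tick marks, a digit-2 glyph on each axis, the "F/Vex" locator label at the
panel corner, unrelated text elsewhere on the page, and the curve as a
2-px stroke — using a bitmap font bundled in code, and returns the exact
calibration used. The default layout renders at 40 px/L and 20 px/(L/s) on
a 560×720 page. `generateCohort()` draws angle-at-B values from the two
published group Gaussians (flattening 144.8 ± 8.5°, non-flattening
163.8 ± 14.1°), truncated to the attainable range, holds the A–B
inclination fixed at 60°, and runs each implied curve through the real
index chain.

What the fixtures do **not** emulate: anti-aliased or colored strokes,
multi-effort overlays, cough artifacts, obstructive loop shapes, grid
lines, scanner noise, or layout drift. Passing the end-to-end tests
therefore demonstrates that the chain is correct on clean fixed-layout
renderings — the regime the method was designed for — not that it is
robust to arbitrary report quality; on real reports the quality flags in
the batch manifest and clinician review remain essential.

## Numerical choices

* Hash: 64-bit average hash; acceptance threshold 4 bits; floor-based
  8-block partition so templates and windows use identical block bounds.
* Intensity threshold 128 (configurable for lighter strokes).
* Angles computed via inclinations; the test suite checks them to 1e-9
  degrees against an arccos-of-direction-vectors oracle.
* Segment fits are exact OLS (closed form); RMSE is reported per fit.
* Log base 10 for the normalized-slope index, matching the scale on which
  its distribution is approximately Gaussian.
* Sizes used by the checks: 20 rendered pages for the end-to-end error
  distribution; 500 + 500 subjects for cutoff recovery; 151-sample curves
  (dense 4001-sample grids for smooth-shape ground truth).

## Known limitations

* No vector-PDF path extraction and no in-package PDF rasterization.
* The locator label and digit glyph must exist on the page at the
  template's rendering scale; reports with other layouts need their own
  templates (`glyphTemplate()` accepts any raster).
* Angles depend on the aspect convention; comparisons across cohorts must
  fix one.
* Reference-equation modelling of the indices (age/height/sex) is out of
  scope, as is any interpretation of CT images: CT labels enter only as
  binary inputs to concordance.
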