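# fvlSAD

Small-airway-disease indices from digitized flow-volume loops.

Small airways (peripheral airways < 2 mm) can be diseased without lowering
FEV1/FVC; what gives them away is an abnormally flat late-expiratory limb
of the flow-volume loop (FVL), traditionally judged by eye with poor
inter-rater agreement. `fvlSAD` is for pulmonary-function researchers and
PFT pipeline builders who want that judgement to be a number. It

* **digitizes** the expiratory limb straight from rendered PFT report
  pages (PNG/TIFF): the FVL panel is found by sliding-window
  perceptual-hash matching of its locator label, the axes are calibrated
  from a digit glyph at a known tick plus the detected axis origin, and
  the curve is traced by intensity thresholding;
* **quantifies** late-expiratory flattening from landmarks
  A (peak expiratory flow), B (the FEF75 locus, at 75 % of the expiratory
  vital capacity) and C (the end of the limb on the volume axis), with OLS
  lines fitted to the A–B and B–C spans and, writing θ = arctan(|slope|/aspect),
  - **∠ABC** = 180° − (θ_AB − θ_BC), the interior angle at B (smaller = flatter),
  - **∠BCX** = θ_BC, the tail's inclination against the volume axis,
  - **log(BC/A-x)** = log10(|slope_BC| / PEF), the peak-flow-normalized tail slope;
* provides the **cohort statistics** used to turn an index into a
  classifier and to validate it: mean − k·SD cutoffs and lower limits of
  normal, strict-inequality flattening classification, concordance rates,
  Fleiss' kappa with large-sample or bootstrap CIs, and the unpaired
  t-test;
* ships a **synthetic-fixtures module** (parametric curves with
  closed-form ground truth, rendered into report-like pages) so the whole
  chain is testable end-to-end without any clinical data, plus a batch
  pipeline (`runBatch()`) and a CLI (`inst/scripts/fvlsad`).

## Worked example

Generate a synthetic limb with known geometry (A–B descent at 60°, B–C at
40°, so true ∠ABC = 180 − (60 − 40) = 160°), render it into a report page,
and digitize it back:

```r
library(fvlSAD)

out <- generateCurve(curveSpec(fvc = 4, vPeak = 0.5,
                               thetaAb = 60, thetaBc = 40))
rr  <- renderReport(out$curve)

reg <- locatePanel(rr$page, fvlLabelTemplate())
#> PanelRegion [196, 560] x [56, 371] (match distance 0)
cal <- calibrateAxes(rr$page, reg, fvlDigitTemplate())
#> PanelCalibration: 0.0250 L/px (origin col 280.00), -0.0500 L/s/px (origin row 280.00)
tr  <- traceCurve(rr$page, reg, cal)
#> ExpiratoryCurve (traced): 159 samples, FVC 4.00 L, PEF 5.15 L/s
computeIndices(tr)
#> SadIndices: angle ABC 160.0 deg, angle BCX 40.0 deg, log(BC/A-x) -0.788
#>   PEF 5.15 L/s, FVC 4.00 L
```

The match distance 0 says the panel label was found exactly; the
calibration recovers the renderer's 40 px/L and 20 px/(L/s) scales; and the
traced curve reproduces the ground-truth angles to a tenth of a degree
(∠ABC 160.0°, ∠BCX 40.0°).

Cutoff arithmetic on a reference (non-flattening) group with mean 163.8°
and SD 14.1°:

```r
refVals <- 163.8 + c(-1, 1) * 14.1 / sqrt(2)  # two points carrying those moments
summarizeCohort(refVals, k = 1)
#> CohortSummary: n = 2, mean 163.80, sd 14.10
#>   cutoff (mean - 1 SD) = 149.70
#>   LLN parametric 140.61, empirical 154.83 (p = 0.05)
```

A value below the 149.7° cutoff is classified as flattening
(`classifyFlattening()`, strict inequality).

## Command line

```sh
fvlsad extract report.png --out curve.csv      # digitize one report page
fvlsad index curve.csv --aspect 1.0            # indices as JSON/CSV
fvlsad cohort indices.csv --column angle_abc_deg --k 1
fvlsad kappa ratings.csv [--bootstrap 2000 --seed 1]
fvlsad concordance a.csv b.csv
fvlsad simulate --n-flat 30 --n-nonflat 60 --seed 7 --out-dir fixtures --render
fvlsad run --inputs reports/ --config cfg.yaml --out-dir results
```

(the script lives at `system.file("scripts", "fvlsad", package = "fvlSAD")`).
Exit codes: 0 success, 2 panel/trace failure, 3 partial batch failure. The
batch run writes an `indices.csv` and a JSON manifest with a per-input
status and a config fingerprint.

## Vignette

`vignettes/flattening-index-methods.Rmd` documents the model, the
landmark/angle conventions, the digitizer's numerical choices, what the
synthetic fixtures do and do not emulate, and known limitations.
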