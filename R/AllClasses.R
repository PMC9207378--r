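#' @import methods
NULL

#' Rendered report page
#'
#' A single grayscale raster page of a pulmonary function test report, the
#' input to panel localization. Pixel values are in \[0, 255\] (0 = ink,
#' 255 = background) with the raster origin at the top-left corner, so row
#' indices increase downward.
#'
#' @slot pixels numeric matrix of intensities in \[0, 255\], rows = y,
#'   columns = x.
#' @slot dpi positive number, the nominal resolution the page was rasterized
#'   at. Purely informational; all geometry is done in pixels.
#' @slot sourceId opaque identifier (typically the file path) carried through
#'   to the digitized curve.
#' @seealso [reportPage()], [readReportPage()], [locatePanel()]
#' @exportClass ReportPage
setClass("ReportPage",
  representation(pixels = "matrix", dpi = "numeric", sourceId = "character"))

setValidity("ReportPage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) < 200L || ncol(p) < 200L)
    return("page must be at least 200 x 200 pixels")
  rng <- range(p)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 255)
    return("pixel intensities must lie in [0, 255]")
  if (length(object@dpi) != 1L || !is.finite(object@dpi) || object@dpi <= 0)
    return("dpi must be a single positive number")
  TRUE
})

#' Glyph template for hash-based localization
#'
#' A small grayscale raster together with its 64-bit average hash, used to
#' find either the panel locator label or an axis digit on a report page by
#' sliding-window perceptual-hash matching.
#'
#' @slot pixels small numeric raster of the glyph.
#' @slot hashBits integer vector of 64 bits (0/1), the average hash of
#'   \code{pixels}.
#' @slot role either \code{"panel_label"} or \code{"axis_digit"}.
#' @slot value the number the glyph represents when \code{role} is
#'   \code{"axis_digit"} (e.g. 2); \code{NA} for labels.
#' @slot tickOffset numeric (dx, dy): pixel displacement from the glyph
#'   anchor (top-left of the matched window) to the axis tick it labels.
#' @seealso [glyphTemplate()], [fvlLabelTemplate()], [fvlDigitTemplate()]
#' @exportClass GlyphTemplate
setClass("GlyphTemplate",
  representation(pixels = "matrix", hashBits = "integer", role = "character",
    value = "numeric", tickOffset = "numeric"))

setValidity("GlyphTemplate", function(object) {
  if (length(object@hashBits) != 64L || !all(object@hashBits %in% c(0L, 1L)))
    return("hashBits must be 64 values in {0, 1}")
  if (!object@role %in% c("panel_label", "axis_digit"))
    return("role must be 'panel_label' or 'axis_digit'")
  if (length(object@tickOffset) != 2L || !all(is.finite(object@tickOffset)))
    return("tickOffset must be two finite numbers")
  TRUE
})

#' Located flow-volume-loop panel
#'
#' Pixel bounds of the FVL panel on a page, produced by [locatePanel()] from
#' the winning label-hash window expanded by the configured margins.
#'
#' @slot x0,y0,x1,y1 inclusive pixel bounds (columns x, rows y).
#' @slot matchDistance Hamming distance of the winning label match (0 for an
#'   exact paste).
#' @exportClass PanelRegion
setClass("PanelRegion",
  representation(x0 = "numeric", y0 = "numeric", x1 = "numeric",
    y1 = "numeric", matchDistance = "numeric"))

setValidity("PanelRegion", function(object) {
  if (object@x0 >= object@x1 || object@y0 >= object@y1)
    return("panel bounds must satisfy x0 < x1 and y0 < y1")
  if (object@matchDistance < 0) return("matchDistance must be >= 0")
  TRUE
})

#' Affine pixel-to-value axis calibration
#'
#' The invertible affine maps from pixel coordinates of a located panel to
#' physical values: volume (L) along columns and flow (L/s) along rows.
#' Because the raster origin is top-left, \code{yScale} is negative (rows
#' increase downward while flow increases upward).
#'
#' @slot xScale litres per pixel column (> 0).
#' @slot xOriginPx pixel column at which volume = 0.
#' @slot yScale litres/second per pixel row (non-zero; negative in the usual
#'   top-left raster convention).
#' @slot yOriginPx pixel row at which flow = 0 (the x-axis).
#' @seealso [calibrateAxes()], [pixelToValue()], [valueToPixel()]
#' @exportClass PanelCalibration
setClass("PanelCalibration",
  representation(xScale = "numeric", xOriginPx = "numeric",
    yScale = "numeric", yOriginPx = "numeric"))

setValidity("PanelCalibration", function(object) {
  if (!is.finite(object@xScale) || object@xScale <= 0)
    return("xScale must be a positive number")
  if (!is.finite(object@yScale) || object@yScale == 0)
    return("yScale must be non-zero")
  TRUE
})

#' Digitized expiratory limb of a flow-volume loop
#'
#' Ordered (volume, flow) samples of the expiratory limb: flow rises to the
#' peak expiratory flow and then decays monotonically to the volume axis.
#' Volume is strictly increasing; flows may dip slightly below zero (tracing
#' noise tolerance 0.05 L/s) and the final sample lies on the volume axis to
#' within the same tolerance.
#'
#' @slot volume numeric, litres, strictly increasing.
#' @slot flow numeric, litres/second.
#' @slot source one of \code{"traced"}, \code{"tabular"}, \code{"synthetic"}.
#' @seealso [expiratoryCurve()], [traceCurve()], [readCurve()],
#'   [computeIndices()]
#' @exportClass ExpiratoryCurve
setClass("ExpiratoryCurve",
  representation(volume = "numeric", flow = "numeric", source = "character"))

.CURVE_EPS <- 0.05

setValidity("ExpiratoryCurve", function(object) {
  v <- object@volume; f <- object@flow
  if (length(v) != length(f)) return("volume and flow must have equal length")
  if (length(v) < 10L) return("curve must have at least 10 samples")
  if (!all(is.finite(v)) || !all(is.finite(f)))
    return("samples must be finite")
  if (any(diff(v) <= 0)) return("volume must be strictly increasing")
  if (any(f < -.CURVE_EPS - 1e-9))
    return(sprintf("flow must be >= -%g L/s", .CURVE_EPS))
  if (abs(f[length(f)]) > .CURVE_EPS + 1e-9)
    return(sprintf("final flow must be within %g L/s of 0", .CURVE_EPS))
  if (!object@source %in% c("traced", "tabular", "synthetic"))
    return("source must be 'traced', 'tabular' or 'synthetic'")
  TRUE
})

#' Landmark points of the expiratory limb
#'
#' The three landmarks of the late-flattening geometry: A is the peak
#' expiratory flow, B the curve point after 75\% of the expiratory vital
#' capacity has been exhaled (the FEF75 locus, linearly interpolated), and C
#' the end of the limb on the volume axis.
#'
#' @slot A,B,C numeric (volume L, flow L/s) pairs.
#' @slot fvc expiratory vital capacity, the volume of C.
#' @seealso [locateLandmarks()]
#' @exportClass Landmarks
setClass("Landmarks",
  representation(A = "numeric", B = "numeric", C = "numeric", fvc = "numeric"),
  prototype(A = c(0.5, 8), B = c(3, 1), C = c(4, 0), fvc = 4))

# new("Landmarks", C = ...) would partial-match new()'s Class argument, so
# landmarks are built by slot assignment on the prototype.
.newLandmarks <- function(A, B, C, fvc) {
  obj <- new("Landmarks")
  obj@A <- A; obj@B <- B; obj@C <- C; obj@fvc <- fvc
  validObject(obj)
  obj
}

setValidity("Landmarks", function(object) {
  for (nm in c("A", "B", "C"))
    if (length(slot(object, nm)) != 2L || !all(is.finite(slot(object, nm))))
      return(sprintf("%s must be a finite (volume, flow) pair", nm))
  if (!(object@A[1] < object@B[1] && object@B[1] < object@C[1]))
    return("landmark volumes must satisfy A < B < C")
  if (abs(object@C[2]) > .CURVE_EPS + 1e-9)
    return("C must lie on the volume axis (|flow| <= 0.05 L/s)")
  TRUE
})

#' Least-squares line fit over a curve segment
#'
#' @slot slope (L/s)/L.
#' @slot intercept L/s.
#' @slot nPoints number of samples used (>= 2).
#' @slot rmse root-mean-square residual, L/s.
#' @slot span (v_start, v_end) volume range of the segment, L.
#' @seealso [fitSegment()]
#' @exportClass SegmentFit
setClass("SegmentFit",
  representation(slope = "numeric", intercept = "numeric",
    nPoints = "integer", rmse = "numeric", span = "numeric"))

setValidity("SegmentFit", function(object) {
  if (object@nPoints < 2L) return("a segment fit needs at least 2 points")
  if (!is.finite(object@rmse) || object@rmse < 0) return("rmse must be >= 0")
  if (length(object@span) != 2L || object@span[1] >= object@span[2])
    return("span must be (v_start, v_end) with v_start < v_end")
  TRUE
})

#' Small-airway-disease flattening indices
#'
#' The three late-expiratory flattening indices of one curve, together with
#' the segment fits and landmarks they derive from: the interior angle at B
#' between the fitted A-B and B-C lines (degrees; smaller = flatter), the
#' inclination of the B-C line against the volume axis (degrees), and the
#' base-10 log of the B-C slope magnitude normalized by peak expiratory
#' flow.
#'
#' @slot angleAbc degrees, in (0, 180].
#' @slot angleBcx degrees, in \[0, 90).
#' @slot logBcOverAx dimensionless (log10).
#' @slot peakFlow L/s, the flow of landmark A ("A-x" vertical distance).
#' @slot fvc L, the volume of landmark C.
#' @slot fitAb,fitBc the two [SegmentFit-class] objects.
#' @slot landmarks the [Landmarks-class] used.
#' @seealso [computeIndices()]
#' @exportClass SadIndices
setClass("SadIndices",
  representation(angleAbc = "numeric", angleBcx = "numeric",
    logBcOverAx = "numeric", peakFlow = "numeric", fvc = "numeric",
    fitAb = "SegmentFit", fitBc = "SegmentFit", landmarks = "Landmarks"))

setValidity("SadIndices", function(object) {
  if (!(object@angleAbc > 0 && object@angleAbc <= 180))
    return("angleAbc must lie in (0, 180]")
  if (!(object@angleBcx >= 0 && object@angleBcx < 90))
    return("angleBcx must lie in [0, 90)")
  if (!is.finite(object@peakFlow) || object@peakFlow <= 0)
    return("peakFlow must be positive")
  TRUE
})

#' Cohort summary of an index
#'
#' Moments and classification cutoffs of a cohort of index values: the
#' mean-minus-k-SD cutoff used for flattening classification and two lower
#' limits of normal (parametric mean - z(p) SD, and the empirical
#' percentile).
#'
#' @slot n number of values.
#' @slot mean,sd sample moments (SD uses the n - 1 denominator).
#' @slot k SD multiplier of the cutoff.
#' @slot percentile probability of the LLN (default 0.05).
#' @slot cutoff mean - k * sd.
#' @slot llnParametric mean - z(percentile) * sd.
#' @slot llnEmpirical interpolated empirical percentile.
#' @seealso [summarizeCohort()]
#' @exportClass CohortSummary
setClass("CohortSummary",
  representation(n = "integer", mean = "numeric", sd = "numeric",
    k = "numeric", percentile = "numeric", cutoff = "numeric",
    llnParametric = "numeric", llnEmpirical = "numeric"))

#' Fleiss' kappa result
#'
#' @slot kappa chance-corrected multi-rater agreement, in \[-1, 1\].
#' @slot ciLower,ciUpper normal-approximation 95\% bounds (or bootstrap
#'   percentile bounds when requested).
#' @slot nSubjects,nRaters panel dimensions.
#' @slot degenerate TRUE when every rater used a single category for every
#'   subject (expected agreement 1; kappa fixed at 1 with a degenerate CI).
#' @seealso [fleissKappa()]
#' @exportClass KappaResult
setClass("KappaResult",
  representation(kappa = "numeric", ciLower = "numeric", ciUpper = "numeric",
    nSubjects = "integer", nRaters = "integer", degenerate = "logical"))

setValidity("KappaResult", function(object) {
  if (object@kappa < -1 - 1e-12 || object@kappa > 1 + 1e-12)
    return("kappa must lie in [-1, 1]")
  if (object@ciLower > object@kappa + 1e-12 ||
      object@ciUpper < object@kappa - 1e-12)
    return("CI must bracket kappa")
  TRUE
})

#' Concordance between two sets of binary calls
#'
#' @slot nTotal number of paired assessments.
#' @slot nConcordant number agreeing.
#' @slot rate nConcordant / nTotal.
#' @seealso [concordanceRate()]
#' @exportClass ConcordanceResult
setClass("ConcordanceResult",
  representation(nTotal = "integer", nConcordant = "integer",
    rate = "numeric"))

setValidity("ConcordanceResult", function(object) {
  if (object@nConcordant < 0L || object@nConcordant > object@nTotal)
    return("0 <= nConcordant <= nTotal must hold")
  if (abs(object@rate - object@nConcordant / object@nTotal) > 1e-12)
    return("rate must equal nConcordant / nTotal")
  TRUE
})
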