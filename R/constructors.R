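#' Construct a ReportPage
#'
#' @param pixels numeric intensity matrix in \[0, 255\], origin top-left.
#' @param dpi nominal resolution (informational).
#' @param sourceId identifier carried into downstream objects.
#' @return a [ReportPage-class] object.
#' @export
reportPage <- function(pixels, dpi = 200, sourceId = "page") {
  new("ReportPage", pixels = pixels, dpi = as.numeric(dpi),
      sourceId = as.character(sourceId))
}

#' Construct a GlyphTemplate
#'
#' Computes and stores the 64-bit average hash of the raster.
#'
#' @param pixels glyph raster (see [textGlyph()]).
#' @param role \code{"panel_label"} or \code{"axis_digit"}.
#' @param value number represented when the glyph is an axis digit.
#' @param tickOffset (dx, dy) from the glyph anchor (matched window
#'   top-left) to the tick it labels.
#' @return a [GlyphTemplate-class] object.
#' @export
glyphTemplate <- function(pixels, role = c("panel_label", "axis_digit"),
                          value = NA_real_, tickOffset = c(0, 0)) {
  role <- match.arg(role)
  new("GlyphTemplate", pixels = pixels, hashBits = hashGlyph(pixels),
      role = role, value = as.numeric(value),
      tickOffset = as.numeric(tickOffset))
}

#' The default panel locator label template ("F/Vex")
#'
#' The expiratory flow-volume panel on the fixture reports carries the text
#' locator "F/Vex" at its top-left corner; its average hash is what
#' [locatePanel()] searches for, mirroring how a fixed-layout clinical
#' report is located by the hash of its panel label.
#'
#' @param scale font upscaling factor (must match the renderer's).
#' @return a [GlyphTemplate-class] with role \code{"panel_label"}.
#' @export
fvlLabelTemplate <- function(scale = 2L) {
  glyphTemplate(textGlyph("F/Vex", scale = scale), role = "panel_label")
}

#' The default axis digit template
#'
#' The digit glyph printed at the value-2 tick of each axis. The stored
#' \code{tickOffset} is the x-axis convention (digit centered under its
#' tick, 5 px below the axis); [calibrateAxes()] derives the y-axis offset
#' from the same placement rule.
#'
#' @param value the digit (default 2).
#' @param scale font upscaling factor.
#' @return a [GlyphTemplate-class] with role \code{"axis_digit"}.
#' @export
fvlDigitTemplate <- function(value = 2, scale = 2L) {
  px <- textGlyph(as.character(value), scale = scale)
  glyphTemplate(px, role = "axis_digit", value = value,
                tickOffset = c(ncol(px) / 2, -5))
}

#' Construct an ExpiratoryCurve
#'
#' @param volume litres, strictly increasing.
#' @param flow litres/second; the final sample must lie on the volume axis
#'   (|flow| <= 0.05 L/s).
#' @param source one of \code{"traced"}, \code{"tabular"},
#'   \code{"synthetic"}.
#' @return an [ExpiratoryCurve-class] object.
#' @export
expiratoryCurve <- function(volume, flow,
                            source = c("tabular", "traced", "synthetic")) {
  source <- match.arg(source)
  new("ExpiratoryCurve", volume = as.numeric(volume), flow = as.numeric(flow),
      source = source)
}

#' @describeIn expiratoryCurve number of samples.
#' @param x,object an ExpiratoryCurve.
#' @export
setMethod("length", "ExpiratoryCurve", function(x) length(x@volume))

#' Curve accessors
#'
#' @param x an [ExpiratoryCurve-class].
#' @return \code{volumes()}: numeric litres; \code{flows()}: numeric L/s.
#' @export
setGeneric("volumes", function(x) standardGeneric("volumes"))

#' @rdname volumes
#' @export
setGeneric("flows", function(x) standardGeneric("flows"))

#' @rdname volumes
#' @export
setMethod("volumes", "ExpiratoryCurve", function(x) x@volume)

#' @rdname volumes
#' @export
setMethod("flows", "ExpiratoryCurve", function(x) x@flow)

#' @export
as.data.frame.ExpiratoryCurve <- function(x, ...) {
  data.frame(volume_L = x@volume, flow_Lps = x@flow)
}

#' Index accessors
#'
#' Extract the individual flattening indices from a [SadIndices-class]
#' object.
#'
#' @param x a SadIndices object (and, for \code{fvc}/\code{peakFlow},
#'   a [Landmarks-class] where noted).
#' @return a single numeric value.
#' @export
setGeneric("angleABC", function(x) standardGeneric("angleABC"))
#' @rdname angleABC
#' @export
setGeneric("angleBCX", function(x) standardGeneric("angleBCX"))
#' @rdname angleABC
#' @export
setGeneric("logBCoverAX", function(x) standardGeneric("logBCoverAX"))
#' @rdname angleABC
#' @export
setGeneric("peakFlow", function(x) standardGeneric("peakFlow"))
#' @rdname angleABC
#' @export
setGeneric("fvc", function(x) standardGeneric("fvc"))

#' @rdname angleABC
#' @export
setMethod("angleABC", "SadIndices", function(x) x@angleAbc)
#' @rdname angleABC
#' @export
setMethod("angleBCX", "SadIndices", function(x) x@angleBcx)
#' @rdname angleABC
#' @export
setMethod("logBCoverAX", "SadIndices", function(x) x@logBcOverAx)
#' @rdname angleABC
#' @export
setMethod("peakFlow", "SadIndices", function(x) x@peakFlow)
#' @rdname angleABC
#' @export
setMethod("fvc", "SadIndices", function(x) x@fvc)
#' @rdname angleABC
#' @export
setMethod("fvc", "Landmarks", function(x) x@fvc)
#' @rdname angleABC
#' @export
setMethod("fvc", "ExpiratoryCurve", function(x) x@volume[length(x@volume)])

setMethod("show", "ReportPage", function(object) {
  cat(sprintf("ReportPage '%s': %d x %d px, %g dpi\n", object@sourceId,
              ncol(object@pixels), nrow(object@pixels), object@dpi))
})

setMethod("show", "PanelRegion", function(object) {
  cat(sprintf("PanelRegion [%g, %g] x [%g, %g] (match distance %g)\n",
              object@x0, object@x1, object@y0, object@y1,
              object@matchDistance))
})

setMethod("show", "PanelCalibration", function(object) {
  cat(sprintf(
    "PanelCalibration: %.4f L/px (origin col %.2f), %.4f L/s/px (origin row %.2f)\n",
    object@xScale, object@xOriginPx, object@yScale, object@yOriginPx))
})

setMethod("show", "ExpiratoryCurve", function(object) {
  n <- length(object@volume)
  cat(sprintf(
    "ExpiratoryCurve (%s): %d samples, FVC %.2f L, PEF %.2f L/s\n",
    object@source, n, object@volume[n], max(object@flow)))
})

setMethod("show", "Landmarks", function(object) {
  cat(sprintf(
    "Landmarks: A (%.2f L, %.2f L/s)  B (%.2f L, %.2f L/s)  C (%.2f L, %.2f L/s)\n",
    object@A[1], object@A[2], object@B[1], object@B[2],
    object@C[1], object@C[2]))
})

setMethod("show", "SegmentFit", function(object) {
  cat(sprintf(
    "SegmentFit over [%.2f, %.2f] L: slope %.4f (L/s)/L, intercept %.4f, n = %d, rmse %.4f\n",
    object@span[1], object@span[2], object@slope, object@intercept,
    object@nPoints, object@rmse))
})

setMethod("show", "SadIndices", function(object) {
  cat(sprintf(
    paste0("SadIndices: angle ABC %.1f deg, angle BCX %.1f deg, ",
           "log(BC/A-x) %.3f\n  PEF %.2f L/s, FVC %.2f L\n"),
    object@angleAbc, object@angleBcx, object@logBcOverAx,
    object@peakFlow, object@fvc))
})

setMethod("show", "CohortSummary", function(object) {
  cat(sprintf(
    paste0("CohortSummary: n = %d, mean %.2f, sd %.2f\n",
           "  cutoff (mean - %g SD) = %.2f\n",
           "  LLN parametric %.2f, empirical %.2f (p = %g)\n"),
    object@n, object@mean, object@sd, object@k, object@cutoff,
    object@llnParametric, object@llnEmpirical, object@percentile))
})

setMethod("show", "KappaResult", function(object) {
  cat(sprintf(
    "Fleiss' kappa %.3f (95%% CI %.3f to %.3f), %d subjects x %d raters%s\n",
    object@kappa, object@ciLower, object@ciUpper, object@nSubjects,
    object@nRaters,
    if (object@degenerate) " [degenerate: single category]" else ""))
})

setMethod("show", "ConcordanceResult", function(object) {
  cat(sprintf("Concordance: %d / %d = %.3f\n", object@nConcordant,
              object@nTotal, object@rate))
})
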