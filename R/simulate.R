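#' Specification of a synthetic expiratory curve
#'
#' Parametric description of an expiratory limb with known ground truth.
#' The \code{piecewise_linear} shape is a straight rise from (0, 0) to the
#' peak A at \code{vPeak}, an A-B descent at inclination \code{thetaAb}
#' (degrees under aspect 1), and a B-C descent at \code{thetaBc}, with B at
#' \code{bFraction * fvc} and C at (fvc, 0). That geometry determines the
#' peak flow: flow(B) = (1 - bFraction) * fvc * tan(thetaBc) and
#' pef = flow(B) + tan(thetaAb) * (bFraction * fvc - vPeak); \code{pef} may
#' therefore be left \code{NA} (derived), and a supplied value that
#' contradicts the geometry is rejected. The \code{smooth_power} shape is
#' flow(v) = pef * ((fvc - v) / (fvc - vPeak))^gamma beyond the peak, with
#' ground truth obtained by running the index chain on a dense noise-free
#' sampling.
#'
#' @param fvc expiratory vital capacity, L.
#' @param vPeak volume at peak flow, L; must satisfy
#'   0 < vPeak < bFraction * fvc.
#' @param thetaAb,thetaBc descent inclinations in degrees,
#'   0 <= thetaBc <= thetaAb < 90.
#' @param pef peak expiratory flow, L/s; \code{NA} = derived
#'   (piecewise_linear) or 8 (smooth_power).
#' @param shape \code{"piecewise_linear"} or \code{"smooth_power"}.
#' @param gamma concavity exponent for smooth_power (> 0).
#' @param noiseSd additive Gaussian flow noise, L/s.
#' @param nSamples number of volume samples (>= 50).
#' @param seed RNG seed for the noise.
#' @param bFraction fraction of FVC locating B (default 0.75).
#' @return a validated list of class \code{"CurveSpec"}; errors with class
#'   \code{fvlInvalidSpec} on inconsistent geometry.
#' @seealso [generateCurve()]
#' @export
curveSpec <- function(fvc, vPeak, thetaAb, thetaBc, pef = NA_real_,
                      shape = c("piecewise_linear", "smooth_power"),
                      gamma = 2, noiseSd = 0, nSamples = 151L, seed = 1L,
                      bFraction = 0.75) {
  shape <- match.arg(shape)
  if (!(fvc > 0 && vPeak > 0 && vPeak < bFraction * fvc))
    .fvlStop("fvlInvalidSpec", "need 0 < vPeak < bFraction * fvc")
  if (!(thetaBc >= 0 && thetaBc <= thetaAb && thetaAb < 90))
    .fvlStop("fvlInvalidSpec", "need 0 <= thetaBc <= thetaAb < 90 degrees")
  if (nSamples < 50L)
    .fvlStop("fvlInvalidSpec", "need at least 50 samples")
  if (noiseSd < 0 || gamma <= 0)
    .fvlStop("fvlInvalidSpec", "noiseSd must be >= 0 and gamma > 0")
  vB <- bFraction * fvc
  fB <- (1 - bFraction) * fvc * tan(thetaBc * pi / 180)
  pefImplied <- fB + tan(thetaAb * pi / 180) * (vB - vPeak)
  if (shape == "piecewise_linear") {
    if (is.na(pef)) {
      pef <- pefImplied
    } else {
      if (fB > pef)
        .fvlStop("fvlInvalidSpec",
                 sprintf("implied flow at B (%.3f) exceeds pef (%.3f)", fB, pef))
      if (abs(pef - pefImplied) > 1e-6 * max(1, pefImplied))
        .fvlStop("fvlInvalidSpec",
                 sprintf("pef %.4f contradicts the segment geometry (implied %.4f)",
                         pef, pefImplied))
    }
  } else if (is.na(pef)) pef <- 8
  if (pef <= 0) .fvlStop("fvlInvalidSpec", "pef must be positive")
  structure(list(fvc = fvc, vPeak = vPeak, thetaAb = thetaAb,
                 thetaBc = thetaBc, pef = pef, shape = shape, gamma = gamma,
                 noiseSd = noiseSd, nSamples = as.integer(nSamples),
                 seed = as.integer(seed), bFraction = bFraction),
            class = "CurveSpec")
}

#' Generate a synthetic expiratory curve with ground truth
#'
#' Samples the curve described by a [curveSpec()] on a uniform volume grid
#' (augmented with the exact peak and B volumes so the piecewise-linear
#' geometry survives sampling), adds seeded Gaussian flow noise if
#' requested (endpoints kept exact, flows clamped at 0), and returns the
#' curve together with its ground-truth indices: closed form for
#' \code{piecewise_linear} (angle at B = 180 - (thetaAb - thetaBc),
#' tail inclination = thetaBc, log10(tan(thetaBc)/pef)), and the index
#' chain run on a dense noise-free sampling for \code{smooth_power}.
#'
#' @param spec a \code{"CurveSpec"}.
#' @return list with \code{curve} (an [ExpiratoryCurve-class], source
#'   \code{"synthetic"}) and \code{truth} (named list: angleAbc, angleBcx,
#'   logBcOverAx, peakFlow, fvc).
#' @examples
#' out <- generateCurve(curveSpec(fvc = 4, vPeak = 0.4, thetaAb = 60,
#'                                thetaBc = 40))
#' out$truth$angleAbc  # 160
#' @export
generateCurve <- function(spec) {
  stopifnot(inherits(spec, "CurveSpec"))
  vB <- spec$bFraction * spec$fvc
  vols <- sort(unique(c(seq(0, spec$fvc, length.out = spec$nSamples),
                        spec$vPeak, vB)))
  flow <- .specFlow(spec, vols)
  if (spec$noiseSd > 0) {
    set.seed(spec$seed)
    inner <- seq_along(flow)[-c(1L, length(flow))]
    flow[inner] <- pmax(0, flow[inner] + stats::rnorm(length(inner),
                                                      sd = spec$noiseSd))
  }
  truth <- if (spec$shape == "piecewise_linear") {
    tanBc <- tan(spec$thetaBc * pi / 180)
    list(angleAbc = 180 - (spec$thetaAb - spec$thetaBc),
         angleBcx = spec$thetaBc,
         logBcOverAx = if (tanBc > 0) log10(tanBc / spec$pef) else NA_real_,
         peakFlow = spec$pef, fvc = spec$fvc)
  } else {
    dense <- sort(unique(c(seq(0, spec$fvc, length.out = 4001L),
                           spec$vPeak, vB)))
    idx <- computeIndices(
      expiratoryCurve(dense, .specFlow(spec, dense), source = "synthetic"),
      bFraction = spec$bFraction)
    list(angleAbc = idx@angleAbc, angleBcx = idx@angleBcx,
         logBcOverAx = idx@logBcOverAx, peakFlow = idx@peakFlow,
         fvc = idx@fvc)
  }
  list(curve = expiratoryCurve(vols, flow, source = "synthetic"),
       truth = truth)
}

# Noise-free flow values of a CurveSpec at the given volumes.
.specFlow <- function(spec, vols) {
  vB <- spec$bFraction * spec$fvc
  if (spec$shape == "piecewise_linear") {
    fB <- (1 - spec$bFraction) * spec$fvc * tan(spec$thetaBc * pi / 180)
    flow <- ifelse(vols <= spec$vPeak,
                   spec$pef * vols / spec$vPeak,
            ifelse(vols <= vB,
                   spec$pef - tan(spec$thetaAb * pi / 180) * (vols - spec$vPeak),
                   fB - tan(spec$thetaBc * pi / 180) * (vols - vB)))
  } else {
    flow <- ifelse(vols <= spec$vPeak,
                   spec$pef * vols / spec$vPeak,
                   spec$pef * ((spec$fvc - vols) /
                               (spec$fvc - spec$vPeak))^spec$gamma)
  }
  pmax(flow, 0)
}

#' Layout of a synthetic report page
#'
#' Geometry of the rendered fixture page: page size, panel bounds, axis
#' origin, pixel-per-unit scales, tick spacing, glyph scale and stroke
#' intensities. The defaults emulate a portrait report page with the
#' expiratory flow-volume panel in the upper right, its "F/Vex" locator
#' label at the panel's top-left corner, tick marks at integer values and a
#' digit glyph at value 2 on each axis.
#'
#' @param pageWidth,pageHeight page size in pixels.
#' @param panel (x0, y0, x1, y1) panel bounds in pixels.
#' @param origin (column, row) of the axis origin (volume 0, flow 0).
#' @param pxPerL pixels per litre on the volume axis.
#' @param pxPerLps pixels per L/s on the flow axis.
#' @param glyphScale integer font upscaling (must match the templates).
#' @param ink,bg stroke and background intensities.
#' @param strokeWidth curve stroke width in pixels.
#' @return a list of class \code{"PageLayout"}.
#' @export
pageLayout <- function(pageWidth = 560L, pageHeight = 720L,
                       panel = c(x0 = 200L, y0 = 60L, x1 = 540L, y1 = 345L),
                       origin = c(col = 280L, row = 280L),
                       pxPerL = 40, pxPerLps = 20, glyphScale = 2L,
                       ink = 0, bg = 255, strokeWidth = 2L) {
  if (panel[1] < 1 || panel[2] < 1 || panel[3] > pageWidth ||
      panel[4] > pageHeight)
    .fvlStop("fvlInvalidLayout", "panel must fit inside the page")
  if (origin[1] <= panel[1] || origin[1] >= panel[3] ||
      origin[2] <= panel[2] || origin[2] >= panel[4])
    .fvlStop("fvlInvalidLayout", "axis origin must lie inside the panel")
  structure(list(pageWidth = as.integer(pageWidth),
                 pageHeight = as.integer(pageHeight),
                 panel = panel, origin = origin, pxPerL = pxPerL,
                 pxPerLps = pxPerLps, glyphScale = as.integer(glyphScale),
                 ink = ink, bg = bg, strokeWidth = as.integer(strokeWidth)),
            class = "PageLayout")
}

# Paste a glyph raster onto the page at (row, col) of its top-left corner;
# only ink pixels overwrite, so glyph padding never erases page content.
.paste <- function(page, glyph, row, col, bg = 255) {
  h <- nrow(glyph); w <- ncol(glyph)
  sub <- page[row:(row + h - 1L), col:(col + w - 1L)]
  inked <- glyph < bg
  sub[inked] <- glyph[inked]
  page[row:(row + h - 1L), col:(col + w - 1L)] <- sub
  page
}

#' Render a curve into a report-like page
#'
#' Draws a synthetic report page: axis lines meeting at the origin, tick
#' marks at integer values, the digit-2 glyph labelling value 2 on each
#' axis, the "F/Vex" panel locator label at the panel's top-left corner,
#' some page dressing outside the panel, the expiratory curve as a stroked
#' polyline, and (optionally) a schematic inspiratory limb below the volume
#' axis. The exact calibration used is returned so the digitizer can be
#' checked against ground truth. Rendering is fully deterministic:
#' identical curve and layout give byte-identical pages.
#'
#' @param curve an [ExpiratoryCurve-class] within the plottable range.
#' @param layout a [pageLayout()].
#' @param sourceId identifier stamped on the page.
#' @param inspiratoryDepth if > 0, draw a half-ellipse inspiratory limb of
#'   this depth (L/s) below the axis.
#' @return list with \code{page} (a [ReportPage-class]) and
#'   \code{calibration} (the ground-truth [PanelCalibration-class]);
#'   errors with class \code{fvlInvalidLayout} when the curve exceeds the
#'   plottable range.
#' @export
renderReport <- function(curve, layout = pageLayout(), sourceId = "synthetic",
                         inspiratoryDepth = 0) {
  stopifnot(is(curve, "ExpiratoryCurve"), inherits(layout, "PageLayout"))
  pn <- layout$panel; org <- layout$origin
  axTopRow <- pn[2] + 22L         # top of the flow axis line
  axEndCol <- pn[3] - 6L          # right end of the volume axis line
  maxVol <- (axEndCol - org[1]) / layout$pxPerL
  maxFlow <- (org[2] - axTopRow - 2L) / layout$pxPerLps
  if (max(curve@volume) > maxVol || max(curve@flow) > maxFlow)
    .fvlStop("fvlInvalidLayout",
             sprintf("curve exceeds plottable range (%.2f L x %.2f L/s)",
                     maxVol, maxFlow))
  page <- matrix(layout$bg, layout$pageHeight, layout$pageWidth)
  ink <- layout$ink; sc <- layout$glyphScale

  # axes
  page[org[2], org[1]:axEndCol] <- ink
  page[axTopRow:org[2], org[1]] <- ink
  # integer ticks: 3 px below the x-axis / left of the y-axis
  for (v in seq_len(floor(maxVol)))
    page[(org[2] + 1L):(org[2] + 3L), org[1] + round(v * layout$pxPerL)] <- ink
  for (f in seq_len(floor(maxFlow)))
    page[org[2] - round(f * layout$pxPerLps),
         (org[1] - 3L):(org[1] - 1L)] <- ink
  # digit glyph at value 2 on each axis
  digit <- textGlyph("2", scale = sc, ink = ink, bg = layout$bg)
  gw <- ncol(digit); gh <- nrow(digit)
  page <- .paste(page, digit,
                 row = org[2] + 5L,
                 col = round(org[1] + 2 * layout$pxPerL - gw / 2),
                 bg = layout$bg)
  page <- .paste(page, digit,
                 row = round(org[2] - 2 * layout$pxPerLps - gh / 2),
                 col = org[1] - gw - 5L,
                 bg = layout$bg)
  # panel locator label and page dressing (outside the panel)
  label <- textGlyph("F/Vex", scale = sc, ink = ink, bg = layout$bg)
  page <- .paste(page, label, row = pn[2] + 6L, col = pn[1] + 6L,
                 bg = layout$bg)
  page <- .paste(page, textGlyph("PFT RePORT", scale = sc, ink = ink,
                                 bg = layout$bg),
                 row = 20L, col = 30L, bg = layout$bg)
  page <- .paste(page, textGlyph("FeV1/FVe 08", scale = sc, ink = ink,
                                 bg = layout$bg),
                 row = 420L, col = 30L, bg = layout$bg)

  # expiratory limb as a stroked polyline in pixel space
  colPx <- org[1] + curve@volume * layout$pxPerL
  rowPx <- org[2] - curve@flow * layout$pxPerLps
  page <- .strokePolyline(page, rowPx, colPx, layout$strokeWidth, ink)
  if (inspiratoryDepth > 0) {
    fvcV <- max(curve@volume)
    vi <- seq(0, fvcV, length.out = 200L)
    fi <- -inspiratoryDepth * sin(pi * vi / fvcV)
    page <- .strokePolyline(page, org[2] - fi * layout$pxPerLps,
                            org[1] + vi * layout$pxPerL,
                            layout$strokeWidth, ink)
  }
  cal <- new("PanelCalibration",
             xScale = 1 / layout$pxPerL, xOriginPx = as.numeric(org[1]),
             yScale = -1 / layout$pxPerLps, yOriginPx = as.numeric(org[2]))
  list(page = reportPage(page, dpi = 200, sourceId = sourceId),
       calibration = cal)
}

# Dense parametric stroke: steps small enough that consecutive points are
# at most half a pixel apart, rounded and thickened downward to the stroke
# width.
.strokePolyline <- function(page, rowPx, colPx, strokeWidth, ink) {
  for (i in seq_len(length(rowPx) - 1L)) {
    steps <- max(2L, ceiling(2 * max(abs(rowPx[i + 1L] - rowPx[i]),
                                     abs(colPx[i + 1L] - colPx[i]))))
    t <- seq(0, 1, length.out = steps)
    rr <- round(rowPx[i] + t * (rowPx[i + 1L] - rowPx[i]))
    cc <- round(colPx[i] + t * (colPx[i + 1L] - colPx[i]))
    for (s in 0:(strokeWidth - 1L)) {
      idx <- cbind(pmin(pmax(rr - s, 1L), nrow(page)),
                   pmin(pmax(cc, 1L), ncol(page)))
      page[idx] <- ink
    }
  }
  page
}

#' Generate a labelled synthetic cohort of indices
#'
#' Draws per-subject angle-at-B values from the two reference Gaussians of
#' the flattening study groups — flattening 144.8 +/- 8.5 degrees,
#' non-flattening 163.8 +/- 14.1 degrees — truncated to the geometrically
#' attainable range, converts each draw to a tail inclination (the A-B
#' inclination is held fixed), generates the corresponding noise-free
#' curve, and runs the index chain on it. Fully seeded and deterministic.
#'
#' @param nFlat,nNonflat group sizes (>= 0).
#' @param seed RNG seed.
#' @param meanFlat,sdFlat,meanNonflat,sdNonflat group Gaussians for the
#'   angle at B, degrees.
#' @param thetaAb fixed A-B inclination, degrees.
#' @param fvc,vPeak,nSamples curve geometry passed to [curveSpec()].
#' @return list with \code{indices} (data.frame: subject, label,
#'   angle_abc_deg, angle_bcx_deg, log_bc_over_ax, peak_flow_lps, fvc_l),
#'   \code{specs} (list of CurveSpec) and \code{labels} (character).
#' @examples
#' coh <- generateCohort(5, 10, seed = 7)
#' table(coh$labels)
#' @export
generateCohort <- function(nFlat, nNonflat, seed = 1L,
                           meanFlat = 144.8, sdFlat = 8.5,
                           meanNonflat = 163.8, sdNonflat = 14.1,
                           thetaAb = 60, fvc = 4, vPeak = 0.5,
                           nSamples = 151L) {
  stopifnot(nFlat >= 0, nNonflat >= 0)
  set.seed(seed)
  lo <- 180 - thetaAb + 0.5   # keep the tail inclination in (0.5, thetaAb)
  hi <- 179.5
  drawTrunc <- function(n, mean, sd) {
    out <- numeric(0)
    while (length(out) < n) {
      x <- stats::rnorm(n, mean, sd)
      out <- c(out, x[x > lo & x < hi])
    }
    out[seq_len(n)]
  }
  ang <- c(drawTrunc(nFlat, meanFlat, sdFlat),
           drawTrunc(nNonflat, meanNonflat, sdNonflat))
  labels <- rep(c("flattening", "non-flattening"), c(nFlat, nNonflat))
  rows <- vector("list", length(ang))
  specs <- vector("list", length(ang))
  for (i in seq_along(ang)) {
    sp <- curveSpec(fvc = fvc, vPeak = vPeak, thetaAb = thetaAb,
                    thetaBc = ang[i] - (180 - thetaAb),
                    nSamples = nSamples, seed = seed + i)
    specs[[i]] <- sp
    idx <- computeIndices(generateCurve(sp)$curve)
    rows[[i]] <- indicesRow(idx, sourceId = sprintf("subject_%03d", i))
  }
  indices <- do.call(rbind, rows)
  indices$subject <- indices$source_id
  indices$label <- labels
  list(indices = indices, specs = specs, labels = labels)
}
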