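#' Locate the flow-volume-loop panel on a report page
#'
#' Slides the label template over the page, computing the 64-bit average
#' hash of every window of the template's size (vectorized via an integral
#' image), and accepts the window with minimum Hamming distance to the
#' label's hash. Ties go to the first window in scan order (leftmost
#' column, then topmost row). The winning window is expanded by the
#' configured margins to the panel bounds.
#'
#' @param page a [ReportPage-class].
#' @param label a [GlyphTemplate-class] with role \code{"panel_label"}.
#' @param threshold maximum acceptable Hamming distance (default 4).
#' @param margin pixels to expand the winning window by, as
#'   (left, top, right, bottom); defaults are sized to the fixture layout
#'   (label at the panel's top-left corner).
#' @return a [PanelRegion-class]; errors with class
#'   \code{fvlPanelNotFound} (reporting the best distance found) when no
#'   window is within \code{threshold}.
#' @examples
#' spec <- curveSpec(fvc = 4, vPeak = 0.6, thetaAb = 60, thetaBc = 40)
#' page <- renderReport(generateCurve(spec)$curve)$page
#' locatePanel(page, fvlLabelTemplate())
#' @seealso [calibrateAxes()], [traceCurve()]
#' @export
locatePanel <- function(page, label, threshold = 4L,
                        margin = c(10, 10, 300, 290)) {
  stopifnot(is(page, "ReportPage"), is(label, "GlyphTemplate"))
  if (label@role != "panel_label")
    .fvlStop("fvlInvalidInput", "template role must be 'panel_label'")
  sr <- .hashSearch(page@pixels, label)
  best <- which.min(sr$dist)  # column-major: leftmost column, then top row
  bd <- sr$dist[best]
  if (bd > threshold)
    .fvlStop("fvlPanelNotFound",
             sprintf("no label window within Hamming distance %d (best: %d)",
                     as.integer(threshold), bd))
  y <- ((best - 1L) %% nrow(sr$dist)) + 1L
  x <- ((best - 1L) %/% nrow(sr$dist)) + 1L
  new("PanelRegion",
      x0 = max(1, x - margin[1]),
      y0 = max(1, y - margin[2]),
      x1 = min(ncol(page@pixels), x + sr$w - 1L + margin[3]),
      y1 = min(nrow(page@pixels), y + sr$h - 1L + margin[4]),
      matchDistance = as.numeric(bd))
}

# Longest run of TRUE per row (or column) of a logical matrix; returns the
# index with the longest run and the run length. Used to find the axis
# lines: inside the panel they are by far the longest straight dark runs.
.longestRun <- function(dark, byRow = TRUE) {
  if (!byRow) dark <- t(dark)
  runs <- apply(dark, 1L, function(z) {
    r <- rle(z)
    w <- r$lengths[r$values]
    if (length(w)) max(w) else 0L
  })
  list(index = which.max(runs), length = max(runs))
}

#' Calibrate panel axes from the digit glyph
#'
#' Finds the axis origin as the intersection of the longest horizontal and
#' longest vertical dark runs inside the panel, then hash-searches for the
#' digit glyph below the x-axis (volume axis) and left of the y-axis (flow
#' axis). Each match, displaced by the tick offset, yields a (pixel, value)
#' pair; together with the origin (value 0) the affine pixel-to-value map
#' of each axis is fit by least squares (a single digit match plus the
#' origin determines it exactly).
#'
#' @param page a [ReportPage-class].
#' @param region the [PanelRegion-class] from [locatePanel()].
#' @param digit a [GlyphTemplate-class] with role \code{"axis_digit"}.
#' @param threshold maximum Hamming distance for a digit match.
#' @param intensityThreshold intensities below this are "ink".
#' @param xTickOffset,yTickOffset (dx, dy) from a matched digit window's
#'   top-left to the tick it labels. Defaults implement the renderer's
#'   placement rule: x-axis digits centered under their tick, y-axis digits
#'   left of theirs; \code{xTickOffset} defaults to the template's stored
#'   offset.
#' @return a [PanelCalibration-class]; errors with class
#'   \code{fvlCalibrationFailed} naming the axis on which the digit was not
#'   found.
#' @export
calibrateAxes <- function(page, region, digit, threshold = 4L,
                          intensityThreshold = 128,
                          xTickOffset = NULL, yTickOffset = NULL) {
  stopifnot(is(page, "ReportPage"), is(region, "PanelRegion"),
            is(digit, "GlyphTemplate"))
  if (digit@role != "axis_digit")
    .fvlStop("fvlInvalidInput", "template role must be 'axis_digit'")
  gw <- ncol(digit@pixels); gh <- nrow(digit@pixels)
  if (is.null(xTickOffset)) xTickOffset <- digit@tickOffset
  if (is.null(yTickOffset)) yTickOffset <- c(gw + 5, gh / 2)

  px <- page@pixels
  rr <- region@y0:region@y1
  cc <- region@x0:region@x1
  dark <- px[rr, cc, drop = FALSE] < intensityThreshold
  axisRow <- rr[.longestRun(dark, byRow = TRUE)$index]
  axisCol <- cc[.longestRun(dark, byRow = FALSE)$index]

  # x-axis digits live in the band below the axis line.
  xm <- tryCatch({
    sr <- .hashSearch(px, digit,
                      rows = c(min(axisRow + 2L, region@y1 - gh), region@y1),
                      cols = c(region@x0, region@x1))
    .hashMatches(sr, threshold)
  }, fvlInvalidInput = function(e) NULL)
  if (is.null(xm) || nrow(xm) == 0L)
    .fvlStop("fvlCalibrationFailed",
             "axis digit not found on the x-axis (volume) band")
  # y-axis digits live in the band left of the axis line.
  ym <- tryCatch({
    sr <- .hashSearch(px, digit,
                      rows = c(region@y0, region@y1),
                      cols = c(region@x0, max(axisCol - 2L, region@x0 + gw)))
    .hashMatches(sr, threshold)
  }, fvlInvalidInput = function(e) NULL)
  if (is.null(ym) || nrow(ym) == 0L)
    .fvlStop("fvlCalibrationFailed",
             "axis digit not found on the y-axis (flow) band")

  # Joint least-squares affine fit per axis: origin carries value 0, every
  # matched tick carries the digit's value.
  xf <- stats::lm.fit(cbind(1, c(axisCol, xm$col + xTickOffset[1])),
                      c(0, rep(digit@value, nrow(xm))))
  yf <- stats::lm.fit(cbind(1, c(axisRow, ym$row + yTickOffset[2])),
                      c(0, rep(digit@value, nrow(ym))))
  xScale <- unname(xf$coefficients[2])
  yScale <- unname(yf$coefficients[2])
  if (!is.finite(xScale) || xScale <= 0)
    .fvlStop("fvlCalibrationFailed", "degenerate x-axis (volume) calibration")
  if (!is.finite(yScale) || yScale == 0)
    .fvlStop("fvlCalibrationFailed", "degenerate y-axis (flow) calibration")
  cal <- new("PanelCalibration",
             xScale = xScale,
             xOriginPx = -unname(xf$coefficients[1]) / xScale,
             yScale = yScale,
             yOriginPx = -unname(yf$coefficients[1]) / yScale)
  # Round-trip sanity: value -> pixel -> value must be exact to well under
  # half a pixel-equivalent on each axis (affine maps are exact).
  rt <- pixelToValue(cal, valueToPixel(cal, 2, 2))
  stopifnot(abs(rt[1] - 2) < 0.5 * abs(xScale),
            abs(rt[2] - 2) < 0.5 * abs(yScale))
  cal
}

#' Map between pixel and value coordinates
#'
#' Affine, exactly invertible maps defined by a [PanelCalibration-class]:
#' volume = (column - xOriginPx) * xScale and
#' flow = (row - yOriginPx) * yScale.
#'
#' @param cal a [PanelCalibration-class].
#' @param xy for \code{pixelToValue} a (column, row) pixel pair (or a
#'   2-column matrix); for \code{valueToPixel} a (volume, flow) pair.
#' @param flow optional second argument so the pair can be passed as two
#'   scalars.
#' @return the mapped pair(s) in the other coordinate system.
#' @export
pixelToValue <- function(cal, xy, flow = NULL) {
  if (!is.null(flow)) xy <- cbind(xy, flow)
  xy <- rbind(xy)
  out <- cbind((xy[, 1] - cal@xOriginPx) * cal@xScale,
               (xy[, 2] - cal@yOriginPx) * cal@yScale)
  if (nrow(out) == 1L) drop(out) else out
}

#' @rdname pixelToValue
#' @export
valueToPixel <- function(cal, xy, flow = NULL) {
  if (!is.null(flow)) xy <- cbind(xy, flow)
  xy <- rbind(xy)
  out <- cbind(xy[, 1] / cal@xScale + cal@xOriginPx,
               xy[, 2] / cal@yScale + cal@yOriginPx)
  if (nrow(out) == 1L) drop(out) else out
}

#' Trace the expiratory limb from a calibrated panel
#'
#' For every pixel column right of the volume origin, curve pixels are
#' separated from the background by a global intensity threshold after
#' masking the calibrated axis row and column. Within a column, the band of
#' greatest flow (topmost contiguous ink run above the x-axis) is taken —
#' the expiratory limb lies above the inspiratory limb — and its centroid
#' row becomes the flow sample. Samples are mapped to value space,
#' volume-ordered and deduplicated by construction (one per column). The
#' trace ends at the last column with curve pixels above the axis; because
#' the final stroke sits about one stroke-width above the axis line, the
#' axis crossing (flow 0) is appended by linear extrapolation of the last
#' two samples (capped at a few pixels), so landmark C lies on the volume
#' axis.
#'
#' @param page a [ReportPage-class].
#' @param region the [PanelRegion-class].
#' @param cal the [PanelCalibration-class].
#' @param intensityThreshold intensities below this are "ink" (default 128;
#'   configurable for lighter strokes).
#' @return an [ExpiratoryCurve-class] with source \code{"traced"}; errors
#'   with class \code{fvlTraceFailed} when fewer than 10 columns are
#'   traceable.
#' @export
traceCurve <- function(page, region, cal, intensityThreshold = 128) {
  stopifnot(is(page, "ReportPage"), is(region, "PanelRegion"),
            is(cal, "PanelCalibration"))
  px <- page@pixels
  axRow <- round(cal@yOriginPx)
  axCol <- round(cal@xOriginPx)
  colIdx <- seq.int(max(axCol + 2L, region@x0), region@x1)
  rowIdx <- seq.int(region@y0, axRow - 1L)  # strictly above the axis line
  if (length(colIdx) < 10L || length(rowIdx) < 2L)
    .fvlStop("fvlTraceFailed", "panel too small to trace")
  ink <- px[rowIdx, colIdx, drop = FALSE] < intensityThreshold
  centroid <- rep(NA_real_, length(colIdx))
  for (j in seq_along(colIdx)) {
    d <- which(ink[, j])
    if (length(d) == 0L) next
    # topmost contiguous band = greatest flow
    brk <- which(diff(d) > 1L)
    top <- if (length(brk)) d[seq_len(brk[1])] else d
    centroid[j] <- mean(rowIdx[top])
  }
  ok <- which(!is.na(centroid))
  if (length(ok) < 10L)
    .fvlStop("fvlTraceFailed",
             sprintf("only %d traceable columns (need >= 10)", length(ok)))
  vol <- (colIdx[ok] - cal@xOriginPx) * cal@xScale
  flo <- (centroid[ok] - cal@yOriginPx) * cal@yScale
  # drop trailing sub-axis noise, then extrapolate the axis crossing
  while (length(flo) > 1L && flo[length(flo)] < 0) {
    vol <- vol[-length(vol)]; flo <- flo[-length(flo)]
  }
  n <- length(flo)
  if (n >= 5L && flo[n] > .CURVE_EPS + 1e-6) {
    # extrapolate the axis crossing from the last few samples (pixel
    # quantization can tie adjacent samples, so a pairwise slope is not
    # reliable); capped at a few pixel-equivalents
    tl <- (n - 4L):n
    sl <- stats::cov(vol[tl], flo[tl]) / stats::var(vol[tl])
    if (is.finite(sl) && sl < 0) {
      dv <- -flo[n] / sl
      if (dv > 0 && dv <= 0.75) {
        vol <- c(vol, vol[n] + dv)
        flo <- c(flo, 0)
      }
    }
  }
  expiratoryCurve(vol, flo, source = "traced")
}

#' Read a report page image
#'
#' Reads a PNG or TIFF page into a [ReportPage-class], converting RGB(A) to
#' grayscale by channel averaging and rescaling to \[0, 255\].
#'
#' @param path image file path (.png, .tif/.tiff).
#' @param dpi nominal resolution to record.
#' @return a [ReportPage-class] with \code{sourceId = path}.
#' @export
readReportPage <- function(path, dpi = 200) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    .fvlStop("fvlInvalidInput",
             sprintf("unsupported image format '.%s' (use PNG or TIFF)", ext)))
  if (length(dim(img)) == 3L)
    img <- apply(img[, , seq_len(min(3L, dim(img)[3])), drop = FALSE],
                 c(1L, 2L), mean)
  reportPage(img * 255, dpi = dpi, sourceId = path)
}

#' Read and write curve tables
#'
#' Curve CSVs have the header \code{volume_L,flow_Lps}, one sample per row,
#' volume ascending. \code{writeCurve} writes 4 decimal places.
#'
#' @param path CSV path.
#' @param curve an [ExpiratoryCurve-class].
#' @return \code{readCurve}: an [ExpiratoryCurve-class] with source
#'   \code{"tabular"}; \code{writeCurve}: the path, invisibly.
#' @export
readCurve <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("volume_L", "flow_Lps") %in% names(df)))
    .fvlStop("fvlInvalidInput",
             "curve CSV must have columns volume_L and flow_Lps")
  expiratoryCurve(df$volume_L, df$flow_Lps, source = "tabular")
}

#' @rdname readCurve
#' @export
writeCurve <- function(curve, path) {
  stopifnot(is(curve, "ExpiratoryCurve"))
  df <- data.frame(volume_L = sprintf("%.4f", curve@volume),
                   flow_Lps = sprintf("%.4f", curve@flow))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
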