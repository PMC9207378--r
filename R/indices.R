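#' Locate landmarks A, B, C on an expiratory curve
#'
#' A is the sample of maximum flow (first such sample on ties: the peak
#' expiratory flow), C the last sample (the end of the limb on the volume
#' axis), and B the curve point at 75\% of the expiratory vital capacity
#' (volume 0.75 * FVC, flow linearly interpolated between the bracketing
#' samples). A must lie before B: a curve whose peak falls at or beyond
#' 75\% of FVC has no A-B descent segment.
#'
#' @param curve an [ExpiratoryCurve-class].
#' @param bFraction fraction of FVC (exhaled volume) locating B; default
#'   0.75, the FEF75 locus.
#' @return a [Landmarks-class]; errors with class \code{fvlDegenerateCurve}
#'   when the peak lies at or beyond B.
#' @examples
#' cv <- generateCurve(curveSpec(fvc = 4, vPeak = 0.4, thetaAb = 60,
#'                               thetaBc = 40))$curve
#' locateLandmarks(cv)
#' @export
locateLandmarks <- function(curve, bFraction = 0.75) {
  stopifnot(is(curve, "ExpiratoryCurve"))
  v <- curve@volume; f <- curve@flow
  n <- length(v)
  ia <- which.max(f)  # first maximum on ties
  fvc <- v[n]
  vB <- bFraction * fvc
  if (v[ia] >= vB)
    .fvlStop("fvlDegenerateCurve",
             sprintf("peak flow at %.3f L is at or beyond %.0f%% of FVC (%.3f L): no A-B segment",
                     v[ia], 100 * bFraction, vB))
  fB <- stats::approx(v, f, xout = vB)$y
  .newLandmarks(A = c(v[ia], f[ia]), B = c(vB, fB), C = c(v[n], f[n]),
                fvc = fvc)
}

#' Ordinary least-squares line over a volume segment
#'
#' Fits flow on volume by OLS over the curve samples with
#' \code{vStart <= volume <= vEnd} (endpoints included), optionally
#' augmented with extra points (the interpolated landmark B is added to
#' both descent segments by [computeIndices()]).
#'
#' @param curve an [ExpiratoryCurve-class], or any data frame / matrix with
#'   volume and flow in the first two columns.
#' @param vStart,vEnd segment bounds in litres.
#' @param extraPoints optional 2-column (volume, flow) matrix appended to
#'   the segment samples.
#' @return a [SegmentFit-class]; errors with class
#'   \code{fvlInsufficientPoints} when fewer than 2 points fall in the
#'   span.
#' @export
fitSegment <- function(curve, vStart, vEnd, extraPoints = NULL) {
  if (is(curve, "ExpiratoryCurve")) {
    v <- curve@volume; f <- curve@flow
  } else {
    m <- as.matrix(curve)
    v <- m[, 1]; f <- m[, 2]
  }
  if (vStart >= vEnd)
    .fvlStop("fvlInvalidInput", "segment requires vStart < vEnd")
  tol <- 1e-9 * max(1, abs(vEnd))
  inSpan <- v >= vStart - tol & v <= vEnd + tol
  v <- v[inSpan]; f <- f[inSpan]
  if (!is.null(extraPoints)) {
    ep <- rbind(extraPoints)
    v <- c(v, ep[, 1]); f <- c(f, ep[, 2])
  }
  keep <- !duplicated(signif(v, 12))
  v <- v[keep]; f <- f[keep]
  if (length(v) < 2L)
    .fvlStop("fvlInsufficientPoints",
             sprintf("only %d sample(s) in [%.3f, %.3f] L (need >= 2)",
                     length(v), vStart, vEnd))
  mv <- mean(v); mf <- mean(f)
  sxx <- sum((v - mv)^2)
  slope <- sum((v - mv) * (f - mf)) / sxx
  intercept <- mf - slope * mv
  res <- f - (intercept + slope * v)
  new("SegmentFit", slope = slope, intercept = intercept,
      nPoints = length(v), rmse = sqrt(mean(res^2)),
      span = c(vStart, vEnd))
}

.slopeOf <- function(x) if (is(x, "SegmentFit")) x@slope else as.numeric(x)

#' Interior angle at B between the fitted A-B and B-C lines
#'
#' The angle at vertex B between the ray toward A (along the A-B line,
#' decreasing volume) and the ray toward C (along the B-C line, increasing
#' volume), computed after rescaling flow by 1/aspect so the angle is taken
#' at a fixed x:y aspect. With descent inclinations
#' theta = atan(|slope|/aspect), the angle equals
#' 180 - (theta_AB - theta_BC) degrees: a flatter tail (smaller |slope_BC|)
#' gives a smaller, more acute angle. Collinear descent gives exactly 180.
#'
#' @param fitAb,fitBc [SegmentFit-class] objects or raw slopes, (L/s)/L.
#' @param aspect flow units per volume unit treated as isometric (default
#'   1: angles in value space with 1 L/s drawn equal to 1 L).
#' @return degrees in (0, 180].
#' @examples
#' abcAngle(-1, 0)           # 135
#' abcAngle(-tan(pi / 3), -tan(pi / 3))  # collinear: 180
#' @export
abcAngle <- function(fitAb, fitBc, aspect = 1) {
  if (!is.finite(aspect) || aspect <= 0)
    .fvlStop("fvlInvalidInput", "aspect must be positive")
  thAb <- atan(-.slopeOf(fitAb) / aspect)
  thBc <- atan(-.slopeOf(fitBc) / aspect)
  180 - abs(thAb - thBc) * 180 / pi
}

#' Inclination of the B-C line against the volume axis
#'
#' @inheritParams abcAngle
#' @return degrees in \[0, 90).
#' @examples
#' bcxAngle(-1)  # 45
#' @export
bcxAngle <- function(fitBc, aspect = 1) {
  if (!is.finite(aspect) || aspect <= 0)
    .fvlStop("fvlInvalidInput", "aspect must be positive")
  atan(abs(.slopeOf(fitBc)) / aspect) * 180 / pi
}

#' Log-ratio of the B-C slope to peak expiratory flow
#'
#' Base-10 log of |slope_BC| / peak flow, the scale-normalized flattening
#' measure (peak flow is the vertical distance between A and the volume
#' axis). The slope magnitude is used so the ratio is positive before the
#' log.
#'
#' @param fitBc a [SegmentFit-class] or raw slope, (L/s)/L.
#' @param peakFlow peak expiratory flow, L/s (> 0).
#' @return dimensionless log10 ratio; errors with class
#'   \code{fvlUndefinedRatio} for a zero slope (rather than returning
#'   -Inf).
#' @examples
#' logBCratio(-0.1, 1)  # -1
#' @export
logBCratio <- function(fitBc, peakFlow) {
  if (!is.finite(peakFlow) || peakFlow <= 0)
    .fvlStop("fvlInvalidInput", "peakFlow must be positive")
  s <- abs(.slopeOf(fitBc))
  if (s == 0)
    .fvlStop("fvlUndefinedRatio",
             "B-C slope is zero: log(BC/A-x) is undefined")
  log10(s / peakFlow)
}

#' Compute all three flattening indices of a curve
#'
#' Locates the landmarks, fits the A-B and B-C segments (each including the
#' interpolated landmark B), and evaluates the three indices. Peak flow is
#' the flow of A.
#'
#' @param curve an [ExpiratoryCurve-class].
#' @param aspect x:y aspect for the angles (see [abcAngle()]).
#' @param bFraction fraction of FVC locating landmark B (default 0.75).
#' @return a [SadIndices-class]; landmark and fit errors propagate.
#' @examples
#' out <- generateCurve(curveSpec(fvc = 4, vPeak = 0.4, thetaAb = 60,
#'                                thetaBc = 30))
#' computeIndices(out$curve)
#' @export
computeIndices <- function(curve, aspect = 1, bFraction = 0.75) {
  lms <- locateLandmarks(curve, bFraction = bFraction)
  bPoint <- rbind(lms@B)
  fitAb <- fitSegment(curve, lms@A[1], lms@B[1], extraPoints = bPoint)
  fitBc <- fitSegment(curve, lms@B[1], lms@C[1], extraPoints = bPoint)
  pef <- lms@A[2]
  new("SadIndices",
      angleAbc = abcAngle(fitAb, fitBc, aspect = aspect),
      angleBcx = bcxAngle(fitBc, aspect = aspect),
      logBcOverAx = logBCratio(fitBc, pef),
      peakFlow = pef, fvc = lms@fvc,
      fitAb = fitAb, fitBc = fitBc, landmarks = lms)
}

#' One-row data frame of a curve's indices
#'
#' Convenience flattening of a [SadIndices-class] (plus fit diagnostics)
#' for batch tables and CSV output.
#'
#' @param idx a [SadIndices-class].
#' @param sourceId identifier for the row.
#' @return a one-row data.frame.
#' @export
indicesRow <- function(idx, sourceId = "curve") {
  stopifnot(is(idx, "SadIndices"))
  data.frame(
    source_id = sourceId,
    angle_abc_deg = idx@angleAbc,
    angle_bcx_deg = idx@angleBcx,
    log_bc_over_ax = idx@logBcOverAx,
    peak_flow_lps = idx@peakFlow,
    fvc_l = idx@fvc,
    ab_slope = idx@fitAb@slope,
    ab_rmse = idx@fitAb@rmse,
    bc_slope = idx@fitBc@slope,
    bc_rmse = idx@fitBc@rmse,
    stringsAsFactors = FALSE)
}
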