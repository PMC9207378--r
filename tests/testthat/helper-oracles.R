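# Independent oracles, deliberately written from the definitions rather
# than via the package's own code paths.

# Interior angle at B from normalized direction vectors and the arccos of
# their dot product (vector-geometry oracle for the inclination formula).
oracleAngleABC <- function(slopeAb, slopeBc, aspect = 1) {
  u <- c(-1, -slopeAb / aspect)   # ray B -> A (decreasing volume)
  v <- c(1, slopeBc / aspect)     # ray B -> C (increasing volume)
  acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
}

# Direct hand expansion of multi-rater agreement: per-subject agreement
# P_i, mean observed agreement, expected agreement from pooled category
# proportions.
oracleFleiss <- function(m) {
  cats <- sort(unique(as.vector(m)))
  n <- nrow(m); r <- ncol(m)
  counts <- t(apply(m, 1, function(row)
    vapply(cats, function(cl) sum(row == cl), numeric(1))))
  Pi <- (rowSums(counts^2) - r) / (r * (r - 1))
  pj <- colSums(counts) / (n * r)
  Pbar <- mean(Pi)
  Pe <- sum(pj^2)
  (Pbar - Pe) / (1 - Pe)
}

# Naive per-window average-hash distance (definition-level sliding scan,
# no integral-image shortcuts) at given window top-left positions.
oracleWindowDistance <- function(pixels, template, rows, cols) {
  th <- hashGlyph(template@pixels)
  h <- nrow(template@pixels); w <- ncol(template@pixels)
  mapply(function(r, cc) {
    win <- pixels[r:(r + h - 1L), cc:(cc + w - 1L)]
    hammingDistance(hashGlyph(win), th)
  }, rows, cols)
}

# A mid-range fixture used by several digitizer tests.
standardFixture <- function(thetaAb = 60, thetaBc = 40, fvc = 4,
                            vPeak = 0.5, ...) {
  out <- generateCurve(curveSpec(fvc = fvc, vPeak = vPeak,
                                 thetaAb = thetaAb, thetaBc = thetaBc, ...))
  c(out, renderReport(out$curve))
}
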