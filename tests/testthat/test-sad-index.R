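# A piecewise-linear curve: rise to (vPeak, pef), then the single straight
# descent flow = pef * (fvc - v) / (fvc - vPeak).
.straightDescent <- function(pef = 8, fvc = 4, vPeak = 0.4, n = 101) {
  v <- sort(unique(c(seq(0, fvc, length.out = n), vPeak, 0.75 * fvc)))
  f <- ifelse(v <= vPeak, pef * v / vPeak, pef * (fvc - v) / (fvc - vPeak))
  expiratoryCurve(v, f, source = "synthetic")
}

test_that("landmarks sit at the peak, the FEF75 locus and the curve end", {
  cv <- .straightDescent(pef = 8, fvc = 4, vPeak = 0.4)
  lm <- locateLandmarks(cv)
  expect_equal(lm@A, c(0.4, 8))
  expect_equal(lm@B[1], 3.0)                 # 0.75 x 4 L
  expect_equal(lm@B[2], 8 * (4 - 3) / 3.6)   # closed form: ~2.222 L/s
  expect_equal(lm@C, c(4, 0))
  expect_equal(fvc(lm), 4)
})

test_that("a flow plateau at the maximum resolves to its first sample", {
  v <- seq(0, 4, length.out = 41)
  f <- approx(c(0, 0.4, 0.6, 4), c(0, 8, 8, 0), xout = v)$y
  lm <- locateLandmarks(expiratoryCurve(v, f, source = "synthetic"))
  expect_equal(lm@A[1], 0.4)
})

test_that("a peak at or beyond 75% of FVC is a degenerate curve", {
  v <- seq(0, 4, length.out = 41)
  f <- approx(c(0, 3.2, 4), c(0, 8, 0), xout = v)$y
  expect_error(locateLandmarks(expiratoryCurve(v, f, source = "synthetic")),
               class = "fvlDegenerateCurve")
})

test_that("segment fits reproduce lines exactly and match lm on noise", {
  cv <- .straightDescent()
  fit <- fitSegment(cv, 0.4, 3.0)
  expect_equal(fit@slope, -8 / 3.6, tolerance = 1e-12)
  expect_equal(fit@rmse, 0, tolerance = 1e-9)

  two <- fitSegment(data.frame(v = c(0, 1), f = c(1, 0)), -1, 2)
  expect_equal(two@slope, -1)
  expect_equal(two@intercept, 1)
  expect_equal(two@nPoints, 2L)

  set.seed(5)
  v <- runif(100, 0, 4)
  f <- 5 - 1.2 * v + rnorm(100, sd = 0.05)
  fit <- fitSegment(cbind(v, f), 0, 4)
  ref <- lm(f ~ v)
  expect_equal(fit@slope, unname(coef(ref)[2]), tolerance = 1e-12)
  expect_equal(fit@intercept, unname(coef(ref)[1]), tolerance = 1e-12)
  se <- summary(ref)$coefficients[2, 2]
  expect_lt(abs(fit@slope - (-1.2)), 3 * se)

  expect_error(fitSegment(cbind(v, f), 10, 11),
               class = "fvlInsufficientPoints")
})

test_that("the interior angle formula agrees with the vector-geometry oracle", {
  expect_equal(abcAngle(-1.5, -1.5), 180)
  expect_equal(abcAngle(-1, 0), 135)
  expect_equal(abcAngle(-tan(60 * pi / 180), -tan(41.5 * pi / 180)), 161.5,
               tolerance = 1e-9)
  set.seed(31)
  for (i in 1:50) {
    sAb <- -tan(runif(1, 0.05, 1.4))
    sBc <- -tan(runif(1, 0, 1.4))
    asp <- runif(1, 0.3, 3)
    expect_equal(abcAngle(sAb, sBc, asp), oracleAngleABC(sAb, sBc, asp),
                 tolerance = 1e-9)
  }
})

test_that("the tail inclination and log-ratio follow their closed forms", {
  expect_equal(bcxAngle(0), 0)
  expect_equal(bcxAngle(-1), 45)
  expect_equal(bcxAngle(-2), atan(2) * 180 / pi, tolerance = 1e-12)
  expect_equal(round(bcxAngle(-2), 3), 63.435)

  expect_equal(logBCratio(-0.1, 1), -1)
  expect_equal(logBCratio(-3.7, 3.7), 0)
  expect_equal(round(logBCratio(-0.14, 1), 3), -0.854)
  expect_error(logBCratio(0, 1), class = "fvlUndefinedRatio")
  expect_error(logBCratio(-1, 0), class = "fvlInvalidInput")
  expect_error(bcxAngle(-1, aspect = -1), class = "fvlInvalidInput")
})

test_that("indices on exact two-segment curves equal their closed forms", {
  for (th in list(c(60, 40), c(55, 10), c(70, 69), c(45, 45))) {
    out <- generateCurve(curveSpec(fvc = 4.2, vPeak = 0.5,
                                   thetaAb = th[1], thetaBc = th[2]))
    idx <- computeIndices(out$curve)
    expect_equal(angleABC(idx), 180 - (th[1] - th[2]), tolerance = 1e-9)
    expect_equal(angleBCX(idx), th[2], tolerance = 1e-9)
    expect_equal(logBCoverAX(idx),
                 log10(tan(th[2] * pi / 180) / out$truth$peakFlow),
                 tolerance = 1e-9)
    expect_equal(peakFlow(idx), out$truth$peakFlow, tolerance = 1e-9)
  }
  # collinear descent: the two fitted segments form a straight line
  idx <- computeIndices(.straightDescent())
  expect_equal(angleABC(idx), 180, tolerance = 1e-9)
})

test_that("a flatter tail strictly shrinks the interior angle", {
  sAb <- -tan(60 * pi / 180)
  tails <- seq(0.05, 55, length.out = 40)
  angs <- vapply(tails, function(th) abcAngle(sAb, -tan(th * pi / 180)),
                 numeric(1))
  expect_true(all(diff(angs) > 0))  # increasing |slope_BC| => larger angle
  # and the generator shows the same ordering end to end
  hi <- computeIndices(generateCurve(curveSpec(4, 0.5, 60, 15))$curve)
  lo <- computeIndices(generateCurve(curveSpec(4, 0.5, 60, 45))$curve)
  expect_lt(angleABC(hi), angleABC(lo))
})

test_that("angles are aspect-scale invariant and the log-ratio is flow-scale invariant", {
  set.seed(13)
  for (i in 1:20) {
    sAb <- -runif(1, 0.5, 3); sBc <- -runif(1, 0.01, 0.5)
    cc <- runif(1, 0.2, 5)
    expect_equal(abcAngle(sAb * cc, sBc * cc, aspect = cc),
                 abcAngle(sAb, sBc, 1), tolerance = 1e-9)
    expect_equal(bcxAngle(sBc * cc, aspect = cc), bcxAngle(sBc, 1),
                 tolerance = 1e-9)
    pef <- runif(1, 2, 10)
    expect_equal(logBCratio(sBc * cc, pef * cc), logBCratio(sBc, pef),
                 tolerance = 1e-12)
  }
})

test_that("angles stay in their admissible ranges on random inputs", {
  set.seed(17)
  for (i in 1:100) {
    sAb <- -tan(runif(1, 0, 1.55))
    sBc <- -tan(runif(1, 0, 1.55))
    a1 <- abcAngle(sAb, sBc)
    a2 <- bcxAngle(sBc)
    expect_true(a1 > 0 && a1 <= 180)
    expect_true(a2 >= 0 && a2 < 90)
  }
})
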