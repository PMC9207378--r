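test_that("axis calibration recovers the renderer's scales", {
  fx <- standardFixture()
  reg <- locatePanel(fx$page, fvlLabelTemplate())
  cal <- calibrateAxes(fx$page, reg, fvlDigitTemplate())
  truth <- fx$calibration
  expect_lt(abs(cal@xScale / truth@xScale - 1), 0.02)
  expect_lt(abs(cal@yScale / truth@yScale - 1), 0.02)
  expect_lt(abs(cal@xOriginPx - truth@xOriginPx), 1)
  expect_lt(abs(cal@yOriginPx - truth@yOriginPx), 1)
})

test_that("calibration is affine to machine precision and invertible", {
  fx <- standardFixture()
  reg <- locatePanel(fx$page, fvlLabelTemplate())
  cal <- calibrateAxes(fx$page, reg, fvlDigitTemplate())
  p1 <- 300; p2 <- 417
  v1 <- pixelToValue(cal, c(p1, 100))[1]
  v2 <- pixelToValue(cal, c(p2, 100))[1]
  expect_equal(v2 - v1, cal@xScale * (p2 - p1), tolerance = 1e-12)
  rt <- pixelToValue(cal, valueToPixel(cal, c(1.7, 3.3)))
  expect_equal(rt, c(1.7, 3.3), tolerance = 1e-12)
})

test_that("an erased x-axis digit fails calibration naming the volume axis", {
  fx <- standardFixture()
  reg <- locatePanel(fx$page, fvlLabelTemplate())
  page <- fx$page@pixels
  # white out the band below the x-axis where the digit lives
  org <- pageLayout()$origin
  page[(org[2] + 4):(org[2] + 25), (org[1] + 60):(org[1] + 100)] <- 255
  err <- tryCatch(
    calibrateAxes(reportPage(page), reg, fvlDigitTemplate()),
    fvlCalibrationFailed = function(e) e)
  expect_s3_class(err, "fvlCalibrationFailed")
  expect_match(conditionMessage(err), "x-axis")
})

test_that("doubling the rendering resolution leaves the value-space calibration unchanged", {
  out <- generateCurve(curveSpec(fvc = 4, vPeak = 0.5, thetaAb = 60,
                                 thetaBc = 40))
  lay1 <- pageLayout()
  lay2 <- pageLayout(pageWidth = 1120L, pageHeight = 1440L,
                     panel = c(x0 = 400L, y0 = 120L, x1 = 1080L, y1 = 690L),
                     origin = c(col = 560L, row = 560L),
                     pxPerL = 80, pxPerLps = 40, glyphScale = 4L,
                     strokeWidth = 4L)
  for (case in list(list(lay = lay1, sc = 2L), list(lay = lay2, sc = 4L))) {
    rr <- renderReport(out$curve, layout = case$lay)
    reg <- locatePanel(rr$page, fvlLabelTemplate(scale = case$sc),
                       margin = c(10, 10, 300, 290) * case$sc / 2)
    cal <- calibrateAxes(rr$page, reg, fvlDigitTemplate(scale = case$sc))
    # value-per-pixel times pixels-per-unit must be 1 on both axes
    expect_lt(abs(cal@xScale * case$lay$pxPerL - 1), 0.02)
    expect_lt(abs(abs(cal@yScale) * case$lay$pxPerLps - 1), 0.02)
  }
})

test_that("tracing a clean rendered curve recovers it to pixel accuracy", {
  fx <- standardFixture()
  reg <- locatePanel(fx$page, fvlLabelTemplate())
  cal <- calibrateAxes(fx$page, reg, fvlDigitTemplate())
  tc <- traceCurve(fx$page, reg, cal)
  expect_s4_class(tc, "ExpiratoryCurve")
  expect_identical(tc@source, "traced")
  # compare traced flow with the synthetic truth at matched volumes:
  # within one pixel-equivalent (plus the half-stroke centroid offset)
  truthFlow <- approx(volumes(fx$curve), flows(fx$curve),
                      xout = volumes(tc), rule = 2)$y
  pxEquiv <- abs(fx$calibration@yScale)
  expect_lt(max(abs(flows(tc) - truthFlow)), 1.5 * pxEquiv)
  # round trip: volume extent and peak flow within 2%
  expect_lt(abs(fvc(tc) / fx$truth$fvc - 1), 0.02)
  expect_lt(abs(max(flows(tc)) / fx$truth$peakFlow - 1), 0.02)
})

test_that("a blank panel fails the trace", {
  page <- matrix(255, 720, 560)
  reg <- new("PanelRegion", x0 = 200, y0 = 60, x1 = 540, y1 = 345,
             matchDistance = 0)
  cal <- new("PanelCalibration", xScale = 1 / 40, xOriginPx = 280,
             yScale = -1 / 20, yOriginPx = 280)
  expect_error(traceCurve(reportPage(page), reg, cal),
               class = "fvlTraceFailed")
})

test_that("an inspiratory limb below the axis never leaks into the trace", {
  out <- generateCurve(curveSpec(fvc = 4, vPeak = 0.5, thetaAb = 60,
                                 thetaBc = 40))
  rr <- renderReport(out$curve, inspiratoryDepth = 3)
  reg <- locatePanel(rr$page, fvlLabelTemplate())
  cal <- calibrateAxes(rr$page, reg, fvlDigitTemplate())
  tc <- traceCurve(rr$page, reg, cal)
  expect_true(all(flows(tc) >= -0.05))
  idx <- computeIndices(tc)
  expect_lt(abs(angleABC(idx) - out$truth$angleAbc), 2)
})

test_that("identical page bytes give identical traced curves", {
  fx1 <- standardFixture(thetaAb = 58, thetaBc = 33)
  fx2 <- standardFixture(thetaAb = 58, thetaBc = 33)
  expect_identical(fx1$page@pixels, fx2$page@pixels)
  trace1 <- traceCurve(fx1$page, locatePanel(fx1$page, fvlLabelTemplate()),
                       calibrateAxes(fx1$page,
                                     locatePanel(fx1$page, fvlLabelTemplate()),
                                     fvlDigitTemplate()))
  trace2 <- traceCurve(fx2$page, locatePanel(fx2$page, fvlLabelTemplate()),
                       calibrateAxes(fx2$page,
                                     locatePanel(fx2$page, fvlLabelTemplate()),
                                     fvlDigitTemplate()))
  expect_identical(volumes(trace1), volumes(trace2))
  expect_identical(flows(trace1), flows(trace2))
})

test_that("curve CSV round-trips through write and read", {
  out <- generateCurve(curveSpec(fvc = 4, vPeak = 0.5, thetaAb = 60,
                                 thetaBc = 40))
  f <- tempfile(fileext = ".csv")
  writeCurve(out$curve, f)
  back <- readCurve(f)
  expect_identical(back@source, "tabular")
  expect_equal(volumes(back), volumes(out$curve), tolerance = 1e-4)
  expect_equal(flows(back), flows(out$curve), tolerance = 1e-4)
  unlink(f)
})
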