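test_that("the generator's closed-form ground truth is internally consistent", {
  out <- generateCurve(curveSpec(fvc = 4, vPeak = 0.6, thetaAb = 60,
                                 thetaBc = 40))
  expect_equal(out$truth$angleAbc, 160)
  expect_equal(out$truth$angleBcx, 40)
  same <- generateCurve(curveSpec(fvc = 4, vPeak = 0.6, thetaAb = 50,
                                  thetaBc = 50))
  expect_equal(same$truth$angleAbc, 180)

  set.seed(77)
  for (i in 1:10) {
    thAb <- runif(1, 40, 75)
    thBc <- runif(1, 5, thAb)
    sp <- curveSpec(fvc = runif(1, 3, 5.5), vPeak = runif(1, 0.3, 1),
                    thetaAb = thAb, thetaBc = thBc)
    idx <- computeIndices(generateCurve(sp)$curve)
    expect_equal(angleABC(idx), 180 - (thAb - thBc), tolerance = 1e-6)
    expect_equal(angleBCX(idx), thBc, tolerance = 1e-6)
  }
})

test_that("a gamma-1 power curve is a single straight descent", {
  sp <- curveSpec(fvc = 4, vPeak = 0.5, thetaAb = 60, thetaBc = 30,
                  shape = "smooth_power", gamma = 1, pef = 7)
  out <- generateCurve(sp)
  expect_equal(out$truth$angleAbc, 180, tolerance = 1e-6)
  idx <- computeIndices(out$curve)
  expect_equal(angleABC(idx), 180, tolerance = 1e-6)
})

test_that("inconsistent specs are rejected", {
  # pef below the flow the geometry implies at B
  expect_error(curveSpec(fvc = 4, vPeak = 0.5, thetaAb = 60, thetaBc = 40,
                         pef = 0.5),
               class = "fvlInvalidSpec")
  expect_error(curveSpec(fvc = 4, vPeak = 3.5, thetaAb = 60, thetaBc = 40),
               class = "fvlInvalidSpec")
  expect_error(curveSpec(fvc = 4, vPeak = 0.5, thetaAb = 40, thetaBc = 60),
               class = "fvlInvalidSpec")
  expect_error(curveSpec(fvc = 4, vPeak = 0.5, thetaAb = 60, thetaBc = 40,
                         nSamples = 20),
               class = "fvlInvalidSpec")
})

test_that("generation and rendering are seeded-deterministic", {
  sp1 <- curveSpec(fvc = 4, vPeak = 0.5, thetaAb = 60, thetaBc = 35,
                   noiseSd = 0.08, seed = 21)
  sp2 <- curveSpec(fvc = 4, vPeak = 0.5, thetaAb = 60, thetaBc = 35,
                   noiseSd = 0.08, seed = 21)
  c1 <- generateCurve(sp1)$curve
  c2 <- generateCurve(sp2)$curve
  expect_identical(flows(c1), flows(c2))
  p1 <- renderReport(c1)$page
  p2 <- renderReport(c2)$page
  expect_identical(p1@pixels, p2@pixels)

  coh1 <- generateCohort(10, 15, seed = 5)
  coh2 <- generateCohort(10, 15, seed = 5)
  expect_identical(coh1$indices, coh2$indices)
})

test_that("noisy curves still satisfy the curve invariants", {
  sp <- curveSpec(fvc = 4, vPeak = 0.5, thetaAb = 60, thetaBc = 35,
                  noiseSd = 0.1, seed = 9)
  cv <- generateCurve(sp)$curve
  expect_true(all(flows(cv) >= -0.05))
  expect_lt(abs(flows(cv)[length(cv)]), 0.05 + 1e-9)
  expect_true(all(diff(volumes(cv)) > 0))
})

test_that("a curve exceeding the plottable range fails to render", {
  out <- generateCurve(curveSpec(fvc = 7, vPeak = 0.5, thetaAb = 60,
                                 thetaBc = 40))
  expect_error(renderReport(out$curve), class = "fvlInvalidLayout")
})

test_that("cohort generation labels and centers its two groups correctly", {
  none <- generateCohort(0, 12, seed = 2)
  expect_true(all(none$labels == "non-flattening"))
  expect_equal(nrow(none$indices), 12L)

  coh <- generateCohort(150, 150, seed = 31)
  ang <- coh$indices$angle_abc_deg
  flat <- coh$labels == "flattening"
  # group means track the target Gaussians within sampling error
  expect_lt(abs(mean(ang[flat]) - 144.8), 2.5)
  expect_lt(abs(mean(ang[!flat]) - 163.8), 3.5)
  # and the flattening group is reliably flatter
  expect_lt(mean(ang[flat]), mean(ang[!flat]))
})
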