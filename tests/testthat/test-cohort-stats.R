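test_that("cohort summary reproduces the mean-minus-SD cutoff arithmetic", {
  # two points constructed to have mean 163.8 and sample SD 14.1 exactly
  vals <- 163.8 + c(-1, 1) * 14.1 / sqrt(2)
  s <- summarizeCohort(vals, k = 1)
  expect_equal(s@mean, 163.8)
  expect_equal(s@sd, 14.1)
  expect_equal(roundHalfUp(s@cutoff, 1), 149.7)

  const <- summarizeCohort(rep(42, 5))
  expect_equal(const@sd, 0)
  expect_equal(const@cutoff, 42)
  expect_equal(const@llnParametric, 42)
  expect_equal(const@llnEmpirical, 42)

  expect_error(summarizeCohort(1), class = "fvlInsufficientData")
})

test_that("cutoff and LLN behave correctly on a known distribution", {
  set.seed(99)
  z <- rnorm(1000)
  s <- summarizeCohort(z, k = 1, percentile = 0.05)
  expect_lt(abs(s@cutoff - (-1)), 0.1)
  expect_lt(abs(s@llnParametric - (-1.6449)), 0.15)
  expect_lt(abs(s@llnEmpirical - (-1.6449)), 0.2)
  # cutoff(k = 0) is the mean and the cutoff strictly decreases in k
  expect_equal(summarizeCohort(z, k = 0)@cutoff, mean(z))
  ks <- seq(0, 3, by = 0.5)
  cuts <- vapply(ks, function(k) summarizeCohort(z, k = k)@cutoff, numeric(1))
  expect_true(all(diff(cuts) < 0))
})

test_that("flattening classification is strict at the cutoff", {
  expect_true(classifyFlattening(144.8, 149.7))
  expect_false(classifyFlattening(149.7, 149.7))
  expect_false(classifyFlattening(163.8, 149.7))
})

test_that("concordance counts matches over totals, symmetrically", {
  a <- rep(c(TRUE, FALSE), c(55, 92))
  b <- rep(c(TRUE, FALSE, FALSE, TRUE), c(26, 29, 44, 48))
  cr <- concordanceRate(a, b)
  expect_equal(cr@nTotal, 147L)
  expect_equal(cr@nConcordant, 70L)
  expect_equal(roundHalfUp(100 * cr@rate, 1), 47.6)

  expect_equal(concordanceRate(a, a)@rate, 1)
  expect_equal(concordanceRate(a, !a)@rate, 0)
  expect_error(concordanceRate(a, b[-1]), class = "fvlInvalidInput")

  set.seed(3)
  perm <- sample.int(147)
  expect_equal(concordanceRate(b, a)@rate, cr@rate)
  expect_equal(concordanceRate(a[perm], b[perm])@rate, cr@rate)
})

test_that("Fleiss' kappa matches the direct agreement expansion", {
  # perfect agreement, both categories present
  perfect <- rbind(c(1, 1, 1), c(0, 0, 0), c(1, 1, 1), c(0, 0, 0))
  expect_equal(fleissKappa(perfect)@kappa, 1)

  # 3 subjects x 3 raters with per-subject counts (3,0), (0,3), (2,1):
  # hand expansion: P = (1 + 1 + 1/3)/3, pj = (5/9, 4/9)
  m <- rbind(c(1, 1, 1), c(0, 0, 0), c(1, 1, 0))
  Pbar <- (1 + 1 + 1 / 3) / 3
  Pe <- (5 / 9)^2 + (4 / 9)^2
  expect_equal(fleissKappa(m)@kappa, (Pbar - Pe) / (1 - Pe),
               tolerance = 1e-12)
  expect_equal(fleissKappa(m)@kappa, oracleFleiss(m), tolerance = 1e-12)

  # maximally split 2-rater panels disagree beyond chance: kappa <= 0
  split2 <- rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1))
  expect_lte(fleissKappa(split2)@kappa, 0)

  # single category everywhere: expected agreement 1, degenerate result
  expect_warning(kd <- fleissKappa(matrix(1, 4, 3)), "single category")
  expect_equal(kd@kappa, 1)
  expect_true(kd@degenerate)
  expect_equal(c(kd@ciLower, kd@ciUpper), c(1, 1))
})

test_that("kappa agrees with the hand formula and is permutation invariant", {
  set.seed(123)
  for (i in 1:100) {
    n <- sample(4:12, 1); r <- sample(2:8, 1)
    m <- matrix(rbinom(n * r, 1, runif(1, 0.2, 0.8)), n, r)
    if (length(unique(as.vector(m))) < 2) next
    k <- fleissKappa(m)@kappa
    expect_equal(k, oracleFleiss(m), tolerance = 1e-12)
    # invariance to permuting raters and subjects
    expect_equal(fleissKappa(m[, sample.int(r)])@kappa, k, tolerance = 1e-12)
    expect_equal(fleissKappa(m[sample.int(n), ])@kappa, k, tolerance = 1e-12)
    # duplicating every subject changes nothing
    expect_equal(fleissKappa(rbind(m, m))@kappa, k, tolerance = 1e-12)
  }
})

test_that("kappa confidence intervals bracket the estimate", {
  set.seed(8)
  m <- matrix(rbinom(160 * 8, 1, 0.6), 160, 8)
  k1 <- fleissKappa(m)
  expect_true(k1@ciLower <= k1@kappa && k1@kappa <= k1@ciUpper)
  k2 <- fleissKappa(m, bootstrap = 200, seed = 4)
  expect_true(k2@ciLower <= k2@kappa && k2@kappa <= k2@ciUpper)
})

test_that("the unpaired t-test wrapper matches the reference and flags degeneracy", {
  x <- c(1, 2, 3, 4)
  same <- twoSampleT(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  expect_error(twoSampleT(rep(0, 4), rep(1, 4)),
               class = "fvlDegenerateVariance")
  expect_error(twoSampleT(1, c(1, 2)), class = "fvlInsufficientData")

  set.seed(10)
  a <- rnorm(50, 0); b <- rnorm(50, 1)
  res <- twoSampleT(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p.value, ref$p.value)
  expect_lt(res$p.value, 0.001)
})

test_that("rating matrices are validated", {
  expect_error(ratingMatrix(matrix(1, 1, 3)), class = "fvlInvalidInput")
  expect_error(ratingMatrix(matrix(c(1, NA, 0, 1), 2, 2)),
               class = "fvlInvalidInput")
})
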