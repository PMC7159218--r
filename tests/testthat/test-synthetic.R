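test_that("generation is deterministic and honours the planted spec", {
  spec <- smallSpec(seed = 3, nTdlus = 4)
  s1 <- generateSlide(spec)
  s2 <- generateSlide(spec)
  expect_identical(s1@image, s2@image)
  expect_identical(pointCoords(s1@truth@acini), pointCoords(s2@truth@acini))
  expect_identical(maskPixels(s1@truth@tdlus), maskPixels(s2@truth@tdlus))

  expect_equal(s1@trueMeasures@nTdlus, 4L)
  expect_length(validateObservations(s1@truth), 0)
  # adipose fraction approximates the target
  frac <- adiposeFraction(s1@truth@adipose, s1@truth@tissue)
  expect_lt(abs(frac - 0.25), 0.05)
  # acini land inside their own TDLU disc
  asg <- assignAcini(s1@truth@acini, s1@truth@tdlus)
  expect_equal(asg$nUnassigned, 0L)
  expect_equal(unname(asg$counts), s1@trueRecords$acini_count_raw)
})

test_that("zero-TDLU slides have empty truth and zero densities", {
  s <- generateSlide(smallSpec(seed = 2, nTdlus = 0))
  expect_equal(max(maskPixels(s@truth@tdlus)), 0L)
  expect_equal(s@trueMeasures@tdlusPerMm2, 0)
  expect_equal(s@trueMeasures@aciniPerMm2, 0)
  expect_true(is.na(s@trueMeasures@medianSpanUm))
  expect_true(is.na(s@trueTypes@predominantType))
})

test_that("planted acini counts map to the expected Russo truth", {
  spec <- smallSpec(seed = 6, nTdlus = 3, aciniPerTdlu = c(5, 12, 81))
  s <- generateSlide(spec)
  expect_setequal(s@trueRecords$acini_count_raw, c(5L, 12L, 81L))
  expect_setequal(s@trueTypes@perTdluTypes, c(1L, 2L, 3L))
})

test_that("infeasible packing requests are rejected", {
  spec <- slideSpec(widthPx = 256, heightPx = 256, resolutionUmPerPx = 2,
                    nTdlus = 10, aciniPerTdlu = rep(5, 10),
                    tdluRadiusUm = 220,
                    acinusRadiusUm = 10,
                    adiposeFractionTarget = 0, seed = 1)
  expect_error(generateSlide(spec), "infeasible packing")
})

test_that("pipeline identity: measuring noiseless truth reproduces the generator's measures", {
  s <- generateSlide(smallSpec(seed = 14, nTdlus = 6))
  res <- computeMeasures(s@truth, defaultCalibration(1))
  tm <- s@trueMeasures; ms <- res$measures
  expect_identical(ms@nTdlus, tm@nTdlus)
  expect_equal(ms@adjustedTissueAreaMm2, tm@adjustedTissueAreaMm2)
  expect_equal(ms@tdlusPerMm2, tm@tdlusPerMm2)
  expect_equal(ms@aciniPerMm2, tm@aciniPerMm2)
  expect_equal(ms@medianAciniPerTdlu, tm@medianAciniPerTdlu)
  expect_equal(ms@medianSpanUm, tm@medianSpanUm, tolerance = 0.02)
  expect_equal(ms@medianTdluAreaMm2, tm@medianTdluAreaMm2, tolerance = 0.02)
})

test_that("perturbation at rate zero is the identity and drops acini at the set rate", {
  s <- generateSlide(smallSpec(seed = 10, nTdlus = 5))
  truth <- s@truth
  same <- perturbObservations(truth, 0, 0, 0, seed = 5)
  expect_identical(pointCoords(same@acini), pointCoords(truth@acini))

  n <- nrow(pointCoords(truth@acini))
  dropped <- perturbObservations(truth, 0.3, 0, 0, seed = 5)
  kept <- nrow(pointCoords(dropped@acini))
  se <- sqrt(n * 0.3 * 0.7)
  expect_lt(abs(kept - 0.7 * n), 4 * se)

  jit <- perturbObservations(truth, 0, 0, jitterUm = 4, seed = 5)
  d <- sqrt(rowSums((pointCoords(jit@acini) - pointCoords(truth@acini))^2))
  expect_gt(mean(d), 0)
  expect_lt(max(d) * 2, 40)   # px at 2 um/px: jitter stays local
})

test_that("the simulated observer reads truth exactly when noiseless and unrestricted", {
  s <- generateSlide(smallSpec(seed = 8, nTdlus = 5))
  obsv <- simulateObserver(s@truth, roiAreaMm2 = 1e4, maxTdlus = 100,
                           seed = 2)
  expect_false(obsv$flagged)
  expect_equal(obsv$nTdlus, 5L)
  expect_equal(obsv$medianAciniPerTdlu,
               stats::median(s@trueRecords$acini_count_raw))
  expect_equal(obsv$medianSpanUm, s@trueMeasures@medianSpanUm,
               tolerance = 0.02)
  # binned adipose is within a half-bin of the true fraction
  frac <- adiposeFraction(s@truth@adipose, s@truth@tissue)
  expect_lt(abs(adiposeFraction(AdiposeEstimate(bin = obsv$adiposeBin)) -
                frac), 0.125 + 1e-9)
})

test_that("observer counting on a hidden scale is recovered by calibration fitting", {
  s <- generateSlide(smallSpec(seed = 4, nTdlus = 8, widthPx = 1024,
                               heightPx = 1024))
  f <- 3.888
  auto <- numeric(); manual <- numeric()
  for (seed in 1:13) {
    o <- simulateObserver(s@truth, roiAreaMm2 = 1e4, maxTdlus = 100,
                          countScale = f, seed = seed)
    raw <- simulateObserver(s@truth, roiAreaMm2 = 1e4, maxTdlus = 100,
                            seed = seed)
    auto <- c(auto, raw$perTdlu$acini_count)
    manual <- c(manual, o$perTdlu$acini_count)
  }
  fit <- fitCalibration(auto[1:100], manual[1:100])
  expect_equal(fit@coefficient, f, tolerance = 0.01)
})

test_that("inter-observer ICC decreases as reading noise grows", {
  s <- generateSlide(smallSpec(seed = 12, nTdlus = 6))
  iccAt <- function(cv) {
    a <- vapply(1:10, function(i)
      simulateObserver(s@truth, 1e4, 100, spanCV = cv, seed = i)$medianSpanUm,
      numeric(1))
    b <- vapply(1:10, function(i)
      simulateObserver(s@truth, 1e4, 100, spanCV = cv,
                       seed = 100 + i)$medianSpanUm, numeric(1))
    # add tiny subject variation via distinct sampled TDLU subsets
    icc31(cbind(a, b))@statistic
  }
  # with a single slide there is no subject variance; instead rate noise on
  # per-TDLU spans across TDLUs as subjects
  spans <- function(cv, seed) {
    o <- simulateObserver(s@truth, 1e4, 100, spanCV = cv, seed = seed)
    o$perTdlu$span_um[order(o$perTdlu$label)]
  }
  iccLow <- icc31(cbind(spans(0.02, 1), spans(0.02, 2)))@statistic
  iccHigh <- icc31(cbind(spans(0.6, 3), spans(0.6, 4)))@statistic
  expect_gt(iccLow, iccHigh)
  expect_gt(iccLow, 0.9)
})
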