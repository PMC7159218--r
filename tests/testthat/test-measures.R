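test_that("tissue area is popcount times pixel area", {
  fr <- SlideFrame(1000, 1000, 1)
  expect_equal(tissueAreaMm2(BinaryMask(fr, matrix(TRUE, 1000, 1000))), 1)
  expect_equal(tissueAreaMm2(BinaryMask(fr, matrix(FALSE, 1000, 1000))), 0)
  set.seed(3)
  m <- matrix(runif(1000 * 1000) > 0.7, 1000, 1000)
  expect_equal(tissueAreaMm2(BinaryMask(fr, m)), sum(m) * 1e-6)
})

test_that("adipose reduces to a fraction under all three representations", {
  obs <- makeToyObservations()
  # constructed mask: adipose block is fully inside tissue
  manual <- sum(maskPixels(obs@adipose) & maskPixels(obs@tissue)) /
    sum(maskPixels(obs@tissue))
  expect_equal(adiposeFraction(obs@adipose, obs@tissue), manual)
  expect_equal(adiposeFraction(obs@tissue, obs@tissue), 1)
  expect_equal(adiposeFraction(AdiposeEstimate(bin = "25-50%")), 0.375)
  expect_equal(adiposeFraction(AdiposeEstimate(bin = "<25%")), 0.125)
  expect_equal(adiposeFraction(AdiposeEstimate(bin = ">75%")), 0.875)
  expect_equal(adiposeFraction(AdiposeEstimate(fraction = 0.42)), 0.42)
  fr <- slideFrame(obs)
  emptyTissue <- BinaryMask(fr, matrix(FALSE, heightPx(fr), widthPx(fr)))
  expect_error(adiposeFraction(obs@adipose, emptyTissue), "empty")
})

test_that("adjusted tissue area applies the non-adipose multiplier", {
  expect_equal(adjustedTissueAreaMm2(50, 0.375), 31.25)
  expect_equal(adjustedTissueAreaMm2(100, 0.25), 75)
  expect_equal(adjustedTissueAreaMm2(7.3, 0), 7.3)
  expect_error(adjustedTissueAreaMm2(10, 1.2), "\\[0, 1\\]")
  expect_error(adjustedTissueAreaMm2(10, -0.1), "\\[0, 1\\]")
})

test_that("moment-ellipse span matches closed forms for discs and rotated ellipses", {
  fr1 <- SlideFrame(1024, 1024, 1)
  # single pixel: zero covariance
  expect_equal(tdluSpanUm(matrix(c(5, 5), 1), fr1), 0)
  # discs: span = diameter
  for (r in c(50, 200)) {
    xy <- discCoords(r)
    expect_equal(tdluSpanUm(xy, fr1), 2 * r, tolerance = 0.02)
  }
  # rotated ellipse: span = 2a, rotation-invariant
  set.seed(11)
  spans <- vapply(runif(5, 0, pi), function(th)
    tdluSpanUm(ellipseCoords(100, 40, th), fr1), numeric(1))
  expect_equal(spans, rep(200, 5), tolerance = 0.02)
  expect_lt(diff(range(spans)) / 200, 0.02)
  # span scales linearly with resolution
  fr2 <- SlideFrame(1024, 1024, 2.5)
  xy <- discCoords(60)
  expect_equal(tdluSpanUm(xy, fr2), 2.5 * tdluSpanUm(xy, fr1))
  expect_error(tdluSpanUm(matrix(numeric(), 0, 2), fr1), "empty")
})

test_that("instance area matches closed form for a rasterized disc", {
  fr <- SlideFrame(512, 512, 1)
  xy <- discCoords(100)
  expect_equal(tdluAreaMm2(xy, fr), pi * 100^2 * 1e-6, tolerance = 0.01)
  fr016 <- SlideFrame(512, 512, 0.16)
  expect_equal(tdluAreaMm2(matrix(c(1, 1), 1), fr016), 2.56e-8)
})

test_that("acini are assigned by centroid containment with unassigned leftovers", {
  obs <- makeToyObservations()
  asg <- assignAcini(obs@acini, obs@tdlus)
  expect_equal(unname(asg$counts), c(3L, 2L))
  expect_equal(asg$nUnassigned, 1L)
  expect_equal(sum(asg$counts) + asg$nUnassigned, nrow(pointCoords(obs@acini)))

  none <- assignAcini(PointSet(slideFrame(obs)), obs@tdlus)
  expect_equal(unname(none$counts), c(0L, 0L))
  expect_equal(none$nUnassigned, 0L)
})

test_that("planted multi-TDLU acini counts are recovered exactly", {
  # three disc TDLUs with 5 / 12 / 81 acini planted at interior positions
  discs <- list(discCoords(30, 40, 40), discCoords(35, 130, 45),
                discCoords(50, 90, 150))
  lm <- coordsToLabelMask(discs)
  fr <- slideFrame(lm)
  set.seed(5)
  plant <- function(xy0, r, n, cx, cy) {
    th <- runif(n, 0, 2 * pi); rr <- (r - 2) * sqrt(runif(n))
    cbind(cx + rr * cos(th), cy + rr * sin(th))
  }
  # centres in mask coordinates: find centroids of each instance
  labs <- maskPixels(lm)
  cent <- lapply(1:3, function(k) {
    idx <- which(labs == k, arr.ind = TRUE)
    c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)
  })
  pts <- rbind(plant(NULL, 28, 5, cent[[1]][1], cent[[1]][2]),
               plant(NULL, 33, 12, cent[[2]][1], cent[[2]][2]),
               plant(NULL, 48, 81, cent[[3]][1], cent[[3]][2]))
  asg <- assignAcini(PointSet(fr, x = pts[, 1], y = pts[, 2]), lm)
  expect_equal(unname(asg$counts), c(5L, 12L, 81L))
  expect_equal(asg$nUnassigned, 0L)
})

test_that("calibration is multiplicative and fitting recovers the factor", {
  expect_equal(calibrate(10), 38.88)
  expect_equal(calibrate(0), 0)
  expect_equal(calibrate(7.7, defaultCalibration(1)), 7.7)

  auto <- c(2, 5, 9, 14, 30)
  fit <- fitCalibration(auto, 3.888 * auto)
  expect_equal(fit@coefficient, 3.888, tolerance = 1e-9)
  expect_equal(fit@source, "fitted")
  # repeated single pair: closed form Sum(a*m)/Sum(a^2)
  fit2 <- fitCalibration(rep(1, 10), rep(5, 10))
  expect_equal(fit2@coefficient, 5)
  # noisy recovery tightens as noise shrinks
  set.seed(21)
  a <- runif(200, 1, 40)
  for (sigma in c(2, 0.01)) {
    f <- fitCalibration(a, 2 * a + rnorm(200, 0, sigma))
    expect_equal(f@coefficient, 2, tolerance = 5 * sigma / 40)
  }
  expect_error(fitCalibration(c(0, 0), c(1, 2)), "degenerate")
  expect_error(fitCalibration(1, 2), "at least 2")
})

test_that("computeMeasures integrates the pipeline on a constructed slide", {
  obs <- makeToyObservations()
  res <- computeMeasures(obs, defaultCalibration(2))
  ms <- res$measures
  tissuePx <- sum(maskPixels(obs@tissue))
  adipPx <- sum(maskPixels(obs@adipose) & maskPixels(obs@tissue))
  adj <- (tissuePx - adipPx) * 1e-6
  expect_equal(ms@adjustedTissueAreaMm2, adj)
  expect_equal(ms@nTdlus, 2L)
  expect_equal(ms@tdlusPerMm2, 2 / adj)
  expect_equal(ms@aciniPerMm2, 6 / adj)   # all detections incl. unassigned
  expect_equal(ms@medianTdluAreaMm2, stats::median(c(400, 900)) * 1e-6)
  # median of raw counts {3, 2} is 2.5, calibrated by 2
  expect_equal(ms@medianAciniPerTdlu, 5)
  # calibration commutes with the median (linearity, checked exactly)
  expect_identical(ms@medianAciniPerTdlu,
                   stats::median(res$records$acini_count_calibrated))
})

test_that("empty-TDLU slides yield zero densities and NA medians with a warning", {
  obs <- makeToyObservations()
  fr <- slideFrame(obs)
  obs@tdlus <- LabelMask(fr, matrix(0L, heightPx(fr), widthPx(fr)))
  expect_warning(res <- computeMeasures(obs), "no TDLUs")
  expect_equal(res$measures@nTdlus, 0L)
  expect_equal(res$measures@tdlusPerMm2, 0)
  expect_true(is.na(res$measures@medianSpanUm))
  expect_true(is.na(res$measures@medianTdluAreaMm2))
  expect_gt(res$measures@aciniPerMm2, 0)
})

test_that("measures are invariant to relabeling and to translating the slide", {
  obs <- makeToyObservations()
  base <- computeMeasures(obs, defaultCalibration(1))$measures

  # swap the two instance labels
  labs <- maskPixels(obs@tdlus)
  swapped <- labs
  swapped[labs == 1L] <- 2L; swapped[labs == 2L] <- 1L
  obs2 <- obs; obs2@tdlus <- LabelMask(slideFrame(obs), swapped)
  alt <- computeMeasures(obs2, defaultCalibration(1))$measures
  expect_equal(as.data.frame(alt), as.data.frame(base))

  # translate everything by (+3, +2) within a larger frame
  fr <- slideFrame(obs)
  w <- widthPx(fr) + 10; h <- heightPx(fr) + 10
  shift <- function(m, fill) {
    out <- matrix(fill, h, w)
    out[3:(heightPx(fr) + 2), 4:(widthPx(fr) + 3)] <- m
    out
  }
  fr2 <- SlideFrame(w, h, resolutionUmPerPx(fr))
  xy <- pointCoords(obs@acini)
  obs3 <- SlideObservations(
    tissue = BinaryMask(fr2, shift(maskPixels(obs@tissue), FALSE)),
    adipose = BinaryMask(fr2, shift(maskPixels(obs@adipose), FALSE)),
    tdlus = LabelMask(fr2, shift(maskPixels(obs@tdlus), 0L)),
    acini = PointSet(fr2, x = xy[, 1] + 3, y = xy[, 2] + 2))
  tr <- computeMeasures(obs3, defaultCalibration(1))$measures
  expect_equal(as.data.frame(tr), as.data.frame(base))
})

test_that("removing adipose lower-bounds densities relative to any positive fraction", {
  obs <- makeToyObservations()
  fr <- slideFrame(obs)
  none <- obs
  none@adipose <- BinaryMask(fr, matrix(FALSE, heightPx(fr), widthPx(fr)))
  d0 <- computeMeasures(none, defaultCalibration(1))$measures@tdlusPerMm2
  for (fracs in c(0.125, 0.5, 0.875)) {
    withFrac <- obs
    withFrac@adipose <- AdiposeEstimate(fraction = fracs)
    d <- computeMeasures(withFrac, defaultCalibration(1))$measures@tdlusPerMm2
    expect_gt(d, d0)
  }
})

test_that("the minimum-area filter excludes instances before all statistics", {
  obs <- makeToyObservations()
  # TDLU 1 is 400 px = 4e-4 mm2; filter it out
  res <- computeMeasures(obs, defaultCalibration(1),
                         minTdluAreaMm2 = 5e-4)
  expect_equal(res$measures@nTdlus, 1L)
  expect_equal(res$records$label, 2L)
  expect_equal(res$measures@medianAciniPerTdlu, 2)   # TDLU 2's count only
})

test_that("semantic masks are split into 4-connected instances", {
  fr <- SlideFrame(20, 20, 1)
  m <- matrix(FALSE, 20, 20)
  m[2:5, 2:5] <- TRUE
  m[10:14, 10:14] <- TRUE
  m[6, 6] <- TRUE   # touches the first block only diagonally
  lm <- labelInstances(BinaryMask(fr, m))
  expect_equal(max(maskPixels(lm)), 3L)
  expect_length(validateObservations(
    SlideObservations(BinaryMask(fr, m), AdiposeEstimate(fraction = 0),
                      lm, PointSet(fr))), 0)
})
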