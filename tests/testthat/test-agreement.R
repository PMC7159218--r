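test_that("detection matching handles exact, empty and planted configurations", {
  fr <- SlideFrame(500, 500, 1)
  set.seed(4)
  gt <- PointSet(fr, x = runif(40, 10, 490), y = runif(40, 10, 490))
  m <- matchDetections(gt, gt, radiusUm = 5)
  expect_equal(m@f1, 1)
  expect_equal(m@tp, 40L)

  none <- matchDetections(PointSet(fr), gt, radiusUm = 5)
  expect_equal(c(none@precision, none@recall, none@f1), c(0, 0, 0))
  expect_equal(none@fn, 40L)

  # 10 gt; 8 preds jittered within radius + 2 far away
  gxy <- cbind(seq(50, 450, length.out = 10), seq(50, 450, length.out = 10))
  gt10 <- PointSet(fr, x = gxy[, 1], y = gxy[, 2])
  pxy <- rbind(gxy[1:8, ] + 2, c(480, 20), c(20, 480))
  pred <- PointSet(fr, x = pxy[, 1], y = pxy[, 2])
  m2 <- matchDetections(pred, gt10, radiusUm = 5)
  expect_equal(m2@precision, 0.8)
  expect_equal(m2@recall, 0.8)
  expect_equal(m2@f1, 0.8)
  expect_equal(sum(m2@pairs[, "pred"] <= 8), 8)
})

test_that("matching is one-to-one, symmetric under swap, and permutation-stable", {
  fr <- SlideFrame(200, 200, 1)
  # two preds near one gt: only one may match
  gt <- PointSet(fr, x = 100, y = 100)
  pred <- PointSet(fr, x = c(99, 101), y = c(100, 100))
  m <- matchDetections(pred, gt, radiusUm = 10)
  expect_equal(m@tp, 1L); expect_equal(m@fp, 1L); expect_equal(m@fn, 0L)

  set.seed(8)
  a <- PointSet(fr, x = runif(30, 5, 195), y = runif(30, 5, 195))
  b <- PointSet(fr, x = runif(25, 5, 195), y = runif(25, 5, 195))
  ab <- matchDetections(a, b, radiusUm = 20)
  ba <- matchDetections(b, a, radiusUm = 20)
  expect_equal(ab@f1, ba@f1)
  expect_equal(ab@precision, ba@recall)
  expect_equal(ab@recall, ba@precision)

  perm <- sample(30)
  xy <- pointCoords(a)[perm, ]
  ap <- PointSet(fr, x = xy[, 1], y = xy[, 2])
  expect_equal(matchDetections(ap, b, radiusUm = 20)@tp, ab@tp)
})

test_that("Dice covers identity, disjoint and partial-overlap cases", {
  fr <- SlideFrame(30, 30, 1)
  blank <- matrix(FALSE, 30, 30)
  a <- blank; a[1:10, 1:10] <- TRUE
  b <- blank; b[1:10, 6:15] <- TRUE     # overlap is a 10x5 strip
  c <- blank; c[20:29, 20:29] <- TRUE
  expect_equal(dice(BinaryMask(fr, a), BinaryMask(fr, a)), 1)
  expect_equal(dice(BinaryMask(fr, a), BinaryMask(fr, c)), 0)
  expect_equal(dice(BinaryMask(fr, a), BinaryMask(fr, b)), 0.5)
  expect_equal(dice(BinaryMask(fr, blank), BinaryMask(fr, blank)), 1)
  expect_error(dice(BinaryMask(fr, a),
                    BinaryMask(SlideFrame(20, 20, 1), matrix(FALSE, 20, 20))),
               "frame")
})

test_that("Dice equals the F1 score computed on pixel sets", {
  fr <- SlideFrame(64, 64, 1)
  set.seed(12)
  for (i in 1:25) {
    a <- matrix(runif(64 * 64) > runif(1, 0.3, 0.9), 64, 64)
    b <- matrix(runif(64 * 64) > runif(1, 0.3, 0.9), 64, 64)
    tp <- sum(a & b); fp <- sum(!a & b); fn <- sum(a & !b)
    f1 <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
    expect_identical(dice(BinaryMask(fr, a), BinaryMask(fr, b)), f1)
  }
})

test_that("ICC(3,1) matches the two-way ANOVA oracle and its invariances", {
  set.seed(31)
  for (i in 1:60) {
    tab <- matrix(rnorm(5 * 3, sd = runif(1, 0.5, 3)), 5, 3)
    expect_equal(icc31(tab)@statistic, iccOracleAov(tab), tolerance = 1e-10)
  }
  # consistency ignores per-rater offsets
  r1 <- rnorm(12)
  res <- icc31(cbind(r1, r1 + 5))
  expect_equal(res@statistic, 1)
  expect_equal(c(res@ciLow, res@ciHigh), c(1, 1))
  # affine rescaling invariance
  tab <- matrix(rnorm(24), 8, 3)
  expect_equal(icc31(2.7 * tab + 13)@statistic, icc31(tab)@statistic,
               tolerance = 1e-10)
  # independent raters -> ICC near zero
  big <- matrix(rnorm(1000), 500, 2)
  expect_lt(abs(icc31(big)@statistic), 0.1)
  # CI brackets the estimate
  expect_true(res@ciLow <= res@statistic && res@statistic <= res@ciHigh)
  r <- icc31(matrix(rnorm(30), 10, 3))
  expect_true(r@ciLow < r@statistic && r@statistic < r@ciHigh)
  expect_error(icc31(matrix(1, 4, 3)), "zero total variance")
  expect_error(icc31(matrix(rnorm(3), 1, 3)), "at least 2")
})

test_that("Fleiss' kappa matches the formula oracle, unanimity and chance levels", {
  set.seed(7)
  for (i in 1:60) {
    n <- sample(2:6, 1)
    counts <- t(stats::rmultinom(8, n, prob = runif(4)))
    k <- fleissKappa(counts, n)
    expect_equal(k@statistic, fleissOracle(counts, n), tolerance = 1e-12)
  }
  # unanimous ratings across >= 2 represented categories
  unan <- rbind(c(4, 0), c(0, 4), c(4, 0), c(0, 4))
  ku <- fleissKappa(unan, 4)
  expect_equal(ku@statistic, 1)
  expect_lt(ku@pValue, 0.01)
  # uniform random raters: kappa ~ 0
  cnt <- t(stats::rmultinom(1000, 3, prob = rep(1 / 3, 3)))
  expect_lt(abs(fleissKappa(cnt, 3)@statistic), 0.05)
  expect_error(fleissKappa(rbind(c(2, 1), c(3, 0)), 4), "sum")
  expect_error(fleissKappa(rbind(c(3, 0), c(3, 0)), 3), "one category")
})

test_that("association-test wrappers expose the standard statistics", {
  x <- 1:20
  expect_equal(associationTest("spearman", x, x^3)$statistic, 0)  # S = 0, rho 1
  expect_equal(suppressWarnings(
    stats::cor.test(x, x^3, method = "spearman"))$estimate[[1]], 1)

  g <- rep(c("a", "b"), each = 10)
  same <- associationTest("mann_whitney_u", rep(1:10, 2), g)
  expect_gt(same$p.value, 0.9)

  kw <- associationTest("kruskal_wallis", c(1:5, 101:105, 201:205),
                        rep(1:3, each = 5))
  expect_lt(kw$p.value, 0.01)

  chi <- associationTest("chi_squared",
                         as.table(matrix(c(20, 0, 0, 20), 2)))
  expect_lt(chi$p.value, 0.01)
  expect_error(associationTest("mann_whitney_u", 1:4, rep("a", 4)),
               "2 groups")
})

test_that("per-slide scores aggregate as mean and SD", {
  a <- aggregateScores(c(0.7, 0.8, 0.9))
  expect_equal(a$mean, 0.8)
  expect_equal(a$sd, stats::sd(c(0.7, 0.8, 0.9)))
  expect_equal(a$n, 3)
})
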