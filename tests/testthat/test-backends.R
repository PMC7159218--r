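test_that("the reference backend recovers planted structures from a noiseless render", {
  s <- generateSlide(smallSpec(seed = 5, nTdlus = 4))
  obs <- runBackend(s@image, slideFrame(s@truth), backendConfig())
  expect_length(validateObservations(obs), 0)

  # TDLU instance count exact
  expect_equal(max(maskPixels(obs@tdlus)), 4L)
  # >= 95% of planted acini found within one acinus radius (<= 16 um)
  m <- matchDetections(obs@acini, s@truth@acini, radiusUm = 16)
  expect_gte(m@recall, 0.95)
  expect_gte(m@precision, 0.95)
  # masks agree with truth nearly perfectly
  sem <- function(o) BinaryMask(slideFrame(o), maskPixels(o@tdlus) > 0L)
  expect_gt(dice(sem(obs), sem(s@truth)), 0.98)
  expect_gt(dice(obs@adipose, s@truth@adipose), 0.98)

  # determinism
  obs2 <- runBackend(s@image, slideFrame(s@truth), backendConfig())
  expect_identical(pointCoords(obs2@acini), pointCoords(obs@acini))
  expect_identical(maskPixels(obs2@tdlus), maskPixels(obs@tdlus))
})

test_that("an all-white image yields empty observations", {
  fr <- SlideFrame(128, 128, 2)
  img <- array(1, dim = c(128, 128, 3))
  obs <- runBackend(img, fr, backendConfig())
  expect_equal(sum(maskPixels(obs@tissue)), 0)
  expect_equal(max(maskPixels(obs@tdlus)), 0L)
  expect_equal(nrow(pointCoords(obs@acini)), 0)
})

test_that("tiling with central-crop stitching reproduces untiled output", {
  # identity and constant per-patch functions
  set.seed(2)
  img <- matrix(runif(300 * 200), 300, 200)
  expect_equal(tileAndStitch(img, 128, 32, function(p) p), img)
  expect_equal(tileAndStitch(img, 128, 32, function(p)
    matrix(7, nrow(p), ncol(p))), matrix(7, 300, 200))

  # a neighbourhood-limited function: 3x3 box mean (context radius 1 <<
  # overlap/2), tiled vs untiled must agree everywhere
  boxf <- function(p) {
    k <- matrix(1 / 9, 3, 3)
    m <- EBImage::filter2(p, k, boundary = "replicate")
    matrix(as.numeric(m), nrow(p), ncol(p))
  }
  full <- boxf(img)
  tiled <- tileAndStitch(img, 128, 32, boxf)
  interior <- tiled[17:284, 17:184]
  expect_equal(interior, full[17:284, 17:184], tolerance = 1e-12)
  expect_error(tileAndStitch(img, 64, 64, function(p) p), "smaller")
})

test_that("reference backend tiled and untiled agree away from borders", {
  s <- generateSlide(smallSpec(seed = 9, nTdlus = 3, widthPx = 512,
                               heightPx = 512))
  img <- s@image
  cls <- function(patch) tdlumetry:::paletteClassify(patch) * 1
  untiled <- cls(img)
  tiled <- tileAndStitch(img, 256, 64, cls)
  expect_identical(tiled, untiled)   # pure per-pixel rule: exact everywhere
})

test_that("a trained pixel classifier segments held-out synthetic adipose", {
  slides <- lapply(c(21, 22, 23), function(sd)
    generateSlide(smallSpec(seed = sd, nTdlus = 1, widthPx = 384,
                            heightPx = 384, adipose = 0.3)))
  cut <- function(s) {
    list(img = s@image[1:256, 1:256, , drop = FALSE],
         mask = maskPixels(s@truth@adipose)[1:256, 1:256])
  }
  tr <- lapply(slides[1:2], cut)
  held <- cut(slides[[3]])
  model <- trainBackend(lapply(tr, `[[`, "img"), lapply(tr, `[[`, "mask"),
                        task = "adipose", seed = 7)
  pred <- predictBackendMask(model, held$img)
  fr <- SlideFrame(256, 256, 2)
  d <- dice(BinaryMask(fr, pred), BinaryMask(fr, held$mask))
  expect_gt(d, 0.8)

  # determinism: same seed, same model predictions
  model2 <- trainBackend(lapply(tr, `[[`, "img"), lapply(tr, `[[`, "mask"),
                         task = "adipose", seed = 7)
  expect_identical(predictBackendMask(model2, held$img), pred)
  expect_error(trainBackend(list(), list()), "empty")
})

test_that("cross-validation folds are balanced, seeded and pure", {
  ids <- sprintf("s%02d", 1:50)
  f5 <- cvFolds(ids, 5, seed = 3)
  expect_equal(as.vector(table(f5)), rep(10L, 5))
  expect_identical(f5, cvFolds(ids, 5, seed = 3))
  expect_false(identical(f5, cvFolds(ids, 5, seed = 4)))
  f9 <- cvFolds(sprintf("s%02d", 1:92), 9, seed = 1)
  expect_true(all(table(f9) %in% c(10L, 11L)))
})
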