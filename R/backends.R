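#' @include synthetic.R
NULL

#' Backend configuration
#'
#' @param backend "reference" (deterministic colour-rule segmenter for the
#'   synthetic renderer's palette) or "classifier" (trained pixel
#'   classifier, see \code{\link{trainBackend}})
#' @param patchSizePx,overlapPx tiling geometry for patch-wise execution
#' @param thresholds named list of reference-backend thresholds:
#'   \code{minRingPx}, \code{maxRingPx} (component size window for acinus
#'   rings) and \code{maxFillRatio} (annularity: rings fill their bounding
#'   disc sparsely, solid blobs fill it)
#' @param model trained classifier object for backend = "classifier"
#' @return config list (class "BackendConfig")
#' @export
backendConfig <- function(backend = c("reference", "classifier"),
                          patchSizePx = 512L, overlapPx = 64L,
                          thresholds = list(minRingPx = 8, maxRingPx = 8000,
                                            maxFillRatio = 0.92),
                          model = NULL) {
  backend <- match.arg(backend)
  if (overlapPx >= patchSizePx)
    stop("overlapPx must be smaller than patchSizePx")
  structure(list(backend = backend, patchSizePx = as.integer(patchSizePx),
                 overlapPx = as.integer(overlapPx),
                 thresholds = thresholds, model = model),
            class = "BackendConfig")
}

# Nearest-palette-colour class map for a rendered synthetic image.
# Returns an integer matrix over the renderer's 6 classes.
paletteClassify <- function(image) {
  pal <- .synPalette
  cols <- rbind(pal$background, pal$stroma, pal$tdlu, pal$adipose,
                pal$ring, pal$lumen)
  h <- dim(image)[1L]; w <- dim(image)[2L]
  n <- h * w
  px <- cbind(as.vector(image[, , 1L]), as.vector(image[, , 2L]),
              as.vector(image[, , 3L]))
  d <- matrix(0, n, nrow(cols))
  for (k in seq_len(nrow(cols)))
    d[, k] <- (px[, 1L] - cols[k, 1L])^2 + (px[, 2L] - cols[k, 2L])^2 +
              (px[, 3L] - cols[k, 3L])^2
  matrix(max.col(-d, ties.method = "first"), h, w)
}

# Acinus centres from a ring mask: connected components filtered on size
# and annularity (rings fill the disc of their outer radius sparsely).
ringCentres <- function(ringMask, thresholds) {
  lab <- EBImage::bwlabel(t(ringMask) * 1)
  lab <- t(matrix(as.integer(lab), nrow(lab), ncol(lab)))
  K <- max(lab)
  if (K == 0L) return(matrix(numeric(), 0L, 2L))
  idx <- which(lab > 0L)
  rc <- arrayInd(idx, dim(lab))
  comp <- lab[idx]
  xs <- rc[, 2L] - 1; ys <- rc[, 1L] - 1
  n <- tabulate(comp, K)
  cx <- tapply(xs, comp, mean); cy <- tapply(ys, comp, mean)
  rmax <- sqrt(tapply((xs - cx[comp])^2 + (ys - cy[comp])^2, comp, max))
  fill <- n / pmax(pi * rmax^2, 1)
  keep <- n >= thresholds$minRingPx & n <= thresholds$maxRingPx &
          fill <= thresholds$maxFillRatio
  cbind(cx, cy)[keep, , drop = FALSE]
}

#' Produce slide observations from an RGB image
#'
#' The pluggable detector/segmenter interface: given an image and its
#' frame, returns the tissue mask, adipose mask, TDLU instance labels and
#' acini point detections that the measures pipeline consumes. Swapping
#' backends changes only these observations, never measure semantics.
#'
#' The \emph{reference} backend classifies pixels by nearest colour in the
#' synthetic renderer's palette: tissue is everything non-background,
#' adipose the adipose colour, the TDLU mask the union of intralobular
#' stroma, epithelial rings and lumina (instances via 4-connected
#' components), and acini the centroids of ring components after size and
#' annularity filtering. It is a deterministic test double tuned to the
#' synthetic palette, not a histology segmenter.
#'
#' The \emph{classifier} backend applies a trained pixel classifier (see
#' \code{\link{trainBackend}}) per task and requires \code{cfg$model}.
#'
#' @param image RGB array (h, w, 3) in [0, 1]
#' @param frame matching \linkS4class{SlideFrame}
#' @param cfg a \code{\link{backendConfig}}
#' @return a \linkS4class{SlideObservations}
#' @export
runBackend <- function(image, frame, cfg = backendConfig()) {
  if (dim(image)[1L] != frame@heightPx || dim(image)[2L] != frame@widthPx)
    stop("image dimensions do not match frame")
  if (cfg$backend == "reference") {
    cls <- paletteClassify(image)
    tissue <- cls != 1L
    adipose <- cls == 4L
    tdluSem <- cls %in% c(3L, 5L, 6L)
    ring <- cls == 5L
  } else {
    if (is.null(cfg$model))
      stop("classifier backend requires a trained model in cfg$model")
    mod <- cfg$model
    tissue <- predictBackendMask(mod$tissue, image)
    adipose <- predictBackendMask(mod$adipose, image) & tissue
    tdluSem <- predictBackendMask(mod$tdlu, image) & tissue
    ring <- predictBackendMask(mod$acini, image)
  }
  dim(tdluSem) <- dim(tissue) <- dim(adipose) <- dim(ring) <-
    c(frame@heightPx, frame@widthPx)
  tdlus <- labelInstances(BinaryMask(frame, tdluSem))
  centres <- ringCentres(ring, cfg$thresholds)
  SlideObservations(
    tissue = BinaryMask(frame, tissue),
    adipose = BinaryMask(frame, adipose),
    tdlus = tdlus,
    acini = PointSet(frame, x = centres[, 1L], y = centres[, 2L]))
}

#' Apply a per-patch function over an image with seam-free stitching
#'
#' Covers the frame with patches of \code{patchSizePx} overlapping by
#' \code{overlapPx} and keeps only each patch's central crop (margin
#' overlap/2, except at the image border), so any per-pixel function that
#' sees at least overlap/2 of context around a pixel produces the same
#' value as it would untiled.
#'
#' @param image matrix or (h, w, c) array
#' @param patchSizePx,overlapPx tiling geometry (overlap < patch size)
#' @param fn function(patch) returning a matrix of the patch's spatial size
#' @return full-frame matrix assembled from central crops
#' @export
tileAndStitch <- function(image, patchSizePx, overlapPx, fn) {
  if (overlapPx >= patchSizePx)
    stop("overlapPx must be smaller than patchSizePx")
  dims <- dim(image)
  h <- dims[1L]; w <- dims[2L]
  out <- matrix(NA_real_, h, w)
  stride <- patchSizePx - overlapPx
  half <- floor(overlapPx / 2)
  ys <- unique(pmin(seq(1L, max(h - patchSizePx + 1L, 1L), by = stride),
                    max(h - patchSizePx + 1L, 1L)))
  if (h > patchSizePx) ys <- unique(c(ys, h - patchSizePx + 1L))
  xs <- unique(pmin(seq(1L, max(w - patchSizePx + 1L, 1L), by = stride),
                    max(w - patchSizePx + 1L, 1L)))
  if (w > patchSizePx) xs <- unique(c(xs, w - patchSizePx + 1L))
  for (y0 in ys) for (x0 in xs) {
    y1 <- min(y0 + patchSizePx - 1L, h); x1 <- min(x0 + patchSizePx - 1L, w)
    patch <- if (length(dims) == 3L) image[y0:y1, x0:x1, , drop = FALSE]
             else image[y0:y1, x0:x1, drop = FALSE]
    res <- fn(patch)
    cy0 <- if (y0 == 1L) 1L else half + 1L
    cy1 <- if (y1 == h) (y1 - y0 + 1L) else (y1 - y0 + 1L) - half
    cx0 <- if (x0 == 1L) 1L else half + 1L
    cx1 <- if (x1 == w) (x1 - x0 + 1L) else (x1 - x0 + 1L) - half
    out[(y0 + cy0 - 1L):(y0 + cy1 - 1L), (x0 + cx0 - 1L):(x0 + cx1 - 1L)] <-
      res[cy0:cy1, cx0:cx1]
  }
  out
}

# Per-pixel features for the trainable backend: raw RGB plus 5x5 and 11x11
# box means of each channel (local context).
pixelFeatures <- function(image) {
  h <- dim(image)[1L]; w <- dim(image)[2L]
  boxMean <- function(m, k) {
    br <- matrix(1 / k^2, k, k)
    as.vector(EBImage::filter2(m, br, boundary = "replicate"))
  }
  feats <- list()
  for (ch in 1:3) {
    m <- image[, , ch]
    feats[[length(feats) + 1L]] <- as.vector(m)
    feats[[length(feats) + 1L]] <- boxMean(m, 5L)
    feats[[length(feats) + 1L]] <- boxMean(m, 11L)
  }
  mat <- do.call(cbind, feats)
  colnames(mat) <- paste0("f", seq_len(ncol(mat)))
  mat
}

#' Train a pixel-classifier segmentation backend on labelled patches
#'
#' Trains a random-forest pixel classifier for one segmentation task
#' (adipose, TDLU, tissue or acinus-ring) from image patches with
#' ground-truth masks. Features are the RGB values and local box means of
#' each channel; training pixels are subsampled per patch. Deterministic
#' given the seed.
#'
#' This trainable backend demonstrates the full train-integrate-measure
#' pipeline at desk scale on synthetic patches; it is a colour/texture
#' classifier, suited to the synthetic renders, not a substitute for a
#' histology-grade segmentation model.
#'
#' @param patches list of RGB arrays (h, w, 3)
#' @param masks list of logical matrices (same sizes): task foreground
#' @param task label recorded with the model
#' @param nTrees random-forest size
#' @param pixelsPerPatch training pixels sampled per patch
#' @param seed RNG seed
#' @return model object (class "tdluPixelClassifier")
#' @export
trainBackend <- function(patches, masks, task = "adipose", nTrees = 50L,
                         pixelsPerPatch = 1500L, seed = 1L) {
  if (!length(patches)) stop("empty training set")
  if (length(patches) != length(masks))
    stop("patches and masks must have equal length")
  withSeed(seed, function() {
    Xs <- list(); ys <- list()
    for (i in seq_along(patches)) {
      f <- pixelFeatures(patches[[i]])
      lab <- as.vector(masks[[i]])
      pick <- sample.int(nrow(f), min(pixelsPerPatch, nrow(f)))
      Xs[[i]] <- f[pick, , drop = FALSE]
      ys[[i]] <- lab[pick]
    }
    X <- do.call(rbind, Xs)
    y <- factor(unlist(ys), levels = c(FALSE, TRUE))
    if (nlevels(droplevels(y)) < 2L)
      stop("training pixels contain a single class; cannot train")
    rf <- randomForest::randomForest(X, y, ntree = nTrees)
    structure(list(rf = rf, task = task, nFeatures = ncol(X)),
              class = "tdluPixelClassifier")
  })
}

#' Segment an image with a trained pixel classifier
#'
#' @param model a "tdluPixelClassifier" from \code{\link{trainBackend}}
#' @param image RGB array (h, w, 3)
#' @return logical matrix (h, w): predicted task foreground
#' @export
predictBackendMask <- function(model, image) {
  stopifnot(inherits(model, "tdluPixelClassifier"))
  f <- pixelFeatures(image)
  pred <- stats::predict(model$rf, f)
  matrix(pred == "TRUE", dim(image)[1L], dim(image)[2L])
}

#' Cross-validation fold assignment by slide
#'
#' Splits slide ids into k folds of near-equal size at random; a pure
#' function of (ids, k, seed). Use each fold in turn as the test set.
#'
#' @param slideIds character or integer vector of slide identifiers
#' @param k number of folds
#' @param seed RNG seed
#' @return integer fold assignment (1..k), named by slide id
#' @export
cvFolds <- function(slideIds, k = 5L, seed = 1L) {
  stopifnot(k >= 2L, length(slideIds) >= k)
  withSeed(seed, function() {
    fold <- rep(seq_len(k), length.out = length(slideIds))
    fold <- sample(fold)
    stats::setNames(fold, as.character(slideIds))
  })
}
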