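#' @include measures.R qualitative.R
NULL

# Renderer palette shared with the reference backend. The pseudo-H&E look:
# white background, pink extra-lobular stroma, lavender intra-lobular
# (TDLU) stroma, near-white adipose, purple acinus epithelium around a
# pale lumen.
.synPalette <- list(
  background = c(1.00, 1.00, 1.00),
  stroma     = c(0.91, 0.73, 0.80),
  tdlu       = c(0.82, 0.68, 0.86),
  adipose    = c(0.965, 0.945, 0.955),
  ring       = c(0.40, 0.22, 0.55),
  lumen      = c(0.95, 0.92, 0.96))

# Indices (into a h x w matrix, (row, col)) of pixels whose centres fall in
# the disc of radius r around (cx, cy), 0-based coordinates.
discIndices <- function(cx, cy, r, w, h) {
  c0 <- max(0L, floor(cx - r)); c1 <- min(w - 1L, ceiling(cx + r))
  r0 <- max(0L, floor(cy - r)); r1 <- min(h - 1L, ceiling(cy + r))
  if (c1 < c0 || r1 < r0) return(integer())
  xs <- c0:c1; ys <- r0:r1
  dx2 <- (xs - cx)^2; dy2 <- (ys - cy)^2
  inside <- outer(dy2, dx2, "+") <= r^2
  rc <- which(inside, arr.ind = TRUE)          # 1-based into the window
  (rc[, 2L] - 1L + c0) * h + (rc[, 1L] - 1L + r0) + 1L   # column-major index
}

# Run fn with a private RNG stream derived from seed; restores .Random.seed.
withSeed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

sampleDist <- function(spec, n) {
  if (is.numeric(spec) && is.null(names(spec))) {
    if (length(spec) == n) return(as.numeric(spec))
    if (length(spec) == 1L) return(rep(as.numeric(spec), n))
    stop("numeric distribution spec must have length 1 or n")
  }
  d <- spec$dist
  out <- switch(d,
    uniform = stats::runif(n, spec$min, spec$max),
    lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog),
    constant = rep(spec$value, n),
    stop("unknown distribution: ", d))
  if (!is.null(spec$min)) out <- pmax(out, spec$min)
  if (!is.null(spec$max)) out <- pmin(out, spec$max)
  out
}

#' Specification of a synthetic slide
#'
#' Describes the geometry the generator plants: a tissue region containing
#' adipose blobs and \code{nTdlus} TDLUs, each a cluster of disc-shaped
#' acini (drawn as epithelial annuli) inside a TDLU disc.
#'
#' Defaults emulate realistic slide-level magnitudes: TDLU spans of roughly
#' 300--800 um, 5--80 acini per TDLU, TDLU densities below ~2 per mm^2, and
#' an adipose content near 30 per cent. The default resolution of 2 um/px
#' corresponds to working at a downsampled magnification, where a few-mm
#' piece of tissue fits in a ~2000 px frame.
#'
#' @param widthPx,heightPx frame size in pixels
#' @param resolutionUmPerPx micrometres per pixel
#' @param nTdlus number of TDLUs to plant
#' @param aciniPerTdlu integer vector (length nTdlus) of planted counts, or
#'   a distribution spec list such as
#'   \code{list(dist = "lognormal", meanlog = log(15), sdlog = 0.7, min = 1,
#'   max = 120)}
#' @param tdluRadiusUm TDLU disc radius (um): numeric or distribution spec.
#'   Radii are enlarged when needed so the requested acini pack into the
#'   disc without overlap.
#' @param acinusRadiusUm acinus radius (um): numeric or distribution spec
#' @param adiposeFractionTarget target adipose fraction of tissue in [0, 1];
#'   the generator approximates it within +/- 0.05
#' @param tissueShape "rectangle" (inset rectangle) or "blob" (perturbed
#'   ellipse)
#' @param seed RNG seed; generation is deterministic given the spec
#' @return a validated spec (class "SlideSpec")
#' @export
slideSpec <- function(widthPx = 2048, heightPx = 2048,
                      resolutionUmPerPx = 2,
                      nTdlus = 8,
                      aciniPerTdlu = list(dist = "lognormal",
                                          meanlog = log(15), sdlog = 0.7,
                                          min = 1, max = 120),
                      tdluRadiusUm = list(dist = "uniform",
                                          min = 150, max = 400),
                      acinusRadiusUm = list(dist = "uniform",
                                            min = 12, max = 20),
                      adiposeFractionTarget = 0.3,
                      tissueShape = c("rectangle", "blob"),
                      seed = 1L) {
  tissueShape <- match.arg(tissueShape)
  stopifnot(widthPx >= 64, heightPx >= 64, resolutionUmPerPx > 0,
            nTdlus >= 0, adiposeFractionTarget >= 0,
            adiposeFractionTarget <= 1)
  spec <- list(widthPx = as.integer(widthPx),
               heightPx = as.integer(heightPx),
               resolutionUmPerPx = resolutionUmPerPx,
               nTdlus = as.integer(nTdlus),
               aciniPerTdlu = aciniPerTdlu,
               tdluRadiusUm = tdluRadiusUm,
               acinusRadiusUm = acinusRadiusUm,
               adiposeFractionTarget = adiposeFractionTarget,
               tissueShape = tissueShape,
               seed = as.integer(seed))
  class(spec) <- "SlideSpec"
  spec
}

#' SyntheticSlide: a rendered pseudo-H&E image with exact ground truth
#'
#' @slot image RGB array (heightPx, widthPx, 3) in [0, 1]
#' @slot truth ground-truth \linkS4class{SlideObservations}
#' @slot trueMeasures \linkS4class{MeasureSet} from the planted geometry
#'   (identity calibration, i.e. raw counting scale)
#' @slot trueRecords per-TDLU data.frame (planted label, area, span, count)
#' @slot trueTypes \linkS4class{QualitativeResult} from planted counts
#' @slot spec the generating spec
#' @exportClass SyntheticSlide
setClass("SyntheticSlide",
  representation(image = "array", truth = "SlideObservations",
                 trueMeasures = "MeasureSet", trueRecords = "data.frame",
                 trueTypes = "QualitativeResult", spec = "list"))

setMethod("show", "SyntheticSlide", function(object) {
  cat(sprintf("SyntheticSlide %d x %d px @ %g um/px, %d TDLU(s), %d acini\n",
              dim(object@image)[2L], dim(object@image)[1L],
              object@truth@frame@resolutionUmPerPx,
              object@trueMeasures@nTdlus,
              nrow(object@truth@acini@coords)))
})

#' Generate a synthetic slide with known ground truth
#'
#' Plants non-overlapping TDLU discs in a tissue region (rejection sampling
#' with bounded retries), fills each with the requested number of
#' non-overlapping acini, adds adipose blobs until the raster adipose
#' fraction approximates the target, renders a pseudo-H&E RGB image, and
#' returns exact ground truth: masks, instance labels, acinus centres, and
#' true measures. Counts in the truth are the planted draws; areas and
#' spans are raster-consistent (span is the planted diameter, which the
#' moment-ellipse span of the rasterized disc matches within 2%).
#'
#' @param spec a \code{\link{slideSpec}}
#' @return a \linkS4class{SyntheticSlide}
#' @export
generateSlide <- function(spec) {
  stopifnot(inherits(spec, "SlideSpec"))
  withSeed(spec$seed, function() .generateSlide(spec))
}

.generateSlide <- function(spec) {
  w <- spec$widthPx; h <- spec$heightPx; res <- spec$resolutionUmPerPx
  frame <- SlideFrame(w, h, res)

  ## tissue region
  tissue <- matrix(FALSE, h, w)
  if (spec$tissueShape == "rectangle") {
    m <- max(2L, round(0.02 * min(w, h)))
    tissue[(m + 1L):(h - m), (m + 1L):(w - m)] <- TRUE
  } else {
    cx <- (w - 1) / 2; cy <- (h - 1) / 2
    a <- 0.46 * w; b <- 0.46 * h
    xs <- 0:(w - 1); ys <- 0:(h - 1)
    ang <- outer(ys - cy, xs - cx, function(dy, dx) atan2(dy, dx))
    wob <- 1 + 0.08 * sin(3 * ang + stats::runif(1, 0, 2 * pi)) +
               0.05 * sin(5 * ang + stats::runif(1, 0, 2 * pi))
    rr <- outer(((ys - cy) / b)^2, ((xs - cx) / a)^2, "+")
    tissue <- rr <= wob^2
  }

  ## distance to tissue boundary (px), for placing structures inside
  dmap <- EBImage::distmap(t(tissue) * 1)          # EBImage is (x, y)
  dmap <- t(matrix(as.numeric(dmap), w, h))

  K <- spec$nTdlus
  aciniCounts <- if (K) as.integer(round(sampleDist(spec$aciniPerTdlu, K)))
                 else integer()
  aciniCounts <- pmax(aciniCounts, 1L)
  acinusR <- sampleDist(spec$acinusRadiusUm, max(K, 1L)) / res  # px
  tdluR <- sampleDist(spec$tdluRadiusUm, max(K, 1L)) / res      # px
  ## enlarge radii that cannot pack their acini (random sequential
  ## placement jams near 0.4 area density)
  if (K) {
    needR <- acinusR * (1.5 + sqrt(aciniCounts / 0.4))
    tdluR <- pmax(tdluR, needR)
  }

  if (K && sum(pi * tdluR^2) > 0.5 * sum(tissue))
    stop("infeasible packing: requested TDLU area exceeds half the tissue")

  centers <- matrix(numeric(), 0L, 2L)
  gap <- 4   # px between TDLU discs
  for (i in seq_len(K)) {
    ok <- FALSE
    eligible <- which(dmap > tdluR[i] + 1)
    if (!length(eligible))
      stop("infeasible packing: TDLU radius exceeds tissue extent")
    for (try in seq_len(3000L)) {
      pick <- eligible[[sample.int(length(eligible), 1L)]]
      cyx <- c((pick - 1L) %% h, (pick - 1L) %/% h)   # (row, col) 0-based
      cand <- c(cyx[2L], cyx[1L])                      # (x, y)
      if (nrow(centers)) {
        d <- sqrt((centers[, 1L] - cand[1L])^2 + (centers[, 2L] - cand[2L])^2)
        if (any(d < tdluR[seq_len(nrow(centers))] + tdluR[i] + gap)) next
      }
      centers <- rbind(centers, cand)
      ok <- TRUE
      break
    }
    if (!ok) stop("infeasible packing: could not place TDLU ", i,
                  " after bounded retries")
  }

  labels <- matrix(0L, h, w)
  for (i in seq_len(K))
    labels[discIndices(centers[i, 1L], centers[i, 2L], tdluR[i], w, h)] <- i

  ## acini inside each TDLU: non-overlapping discs, centres kept one
  ## acinus radius plus a margin inside the TDLU boundary
  aciniXY <- matrix(numeric(), 0L, 2L)
  aciniOwner <- integer()
  aciniRadii <- numeric()
  for (i in seq_len(K)) {
    aR <- acinusR[i]
    maxC <- tdluR[i] - aR - 2
    placed <- matrix(numeric(), 0L, 2L)
    sep <- 2 * aR + 2
    tries <- 0L
    while (nrow(placed) < aciniCounts[i] && tries < 20000L) {
      tries <- tries + 1L
      u <- stats::runif(1); th <- stats::runif(1, 0, 2 * pi)
      rr <- maxC * sqrt(u)
      p <- centers[i, ] + rr * c(cos(th), sin(th))
      if (nrow(placed)) {
        d2 <- (placed[, 1L] - p[1L])^2 + (placed[, 2L] - p[2L])^2
        if (min(d2) < sep^2) {
          if (tries %% 5000L == 0L) sep <- max(2 * aR, sep * 0.95)
          next
        }
      }
      placed <- rbind(placed, p)
    }
    if (nrow(placed) < aciniCounts[i])
      stop("could not place ", aciniCounts[i], " acini in TDLU ", i)
    aciniXY <- rbind(aciniXY, placed)
    aciniOwner <- c(aciniOwner, rep(i, nrow(placed)))
    aciniRadii <- c(aciniRadii, rep(aR, nrow(placed)))
  }

  ## adipose blobs, kept clear of TDLUs, until the raster fraction reaches
  ## the target (within the tolerance the generator guarantees, +/- 0.05)
  adipose <- matrix(FALSE, h, w)
  nTissue <- sum(tissue)
  target <- spec$adiposeFractionTarget
  if (target > 0) {
    ## blob radius 50-150 um, capped so one blob adds at most ~2.5% of the
    ## tissue (keeps the achieved fraction within the +/- 0.05 guarantee
    ## on small frames)
    rCap <- sqrt(0.025 * nTissue / pi)
    blobRpx <- pmin(c(50, 150) / res, c(rCap / 2, rCap))
    eligible <- which(dmap > 2)
    for (try in seq_len(4000L)) {
      frac <- sum(adipose) / nTissue
      if (frac >= target - 0.005) break
      rA <- stats::runif(1, blobRpx[1L], blobRpx[2L])
      pick <- eligible[[sample.int(length(eligible), 1L)]]
      cand <- c((pick - 1L) %/% h, (pick - 1L) %% h)   # (x, y)
      if (K) {
        d <- sqrt((centers[, 1L] - cand[1L])^2 + (centers[, 2L] - cand[2L])^2)
        if (any(d < tdluR + rA + 2)) next
      }
      idx <- discIndices(cand[1L], cand[2L], rA, w, h)
      idx <- idx[tissue[idx]]
      adipose[idx] <- TRUE
    }
    frac <- sum(adipose) / nTissue
    if (abs(frac - target) > 0.05)
      warning(sprintf("adipose fraction %.3f misses target %.3f", frac,
                      target))
  }

  ## render
  pal <- .synPalette
  cls <- matrix(1L, h, w)                 # 1 background
  cls[tissue] <- 2L                       # stroma
  cls[labels > 0L] <- 3L                  # TDLU intralobular stroma
  cls[adipose] <- 4L                      # adipose
  for (j in seq_len(nrow(aciniXY))) {
    aR <- aciniRadii[j]
    ring <- discIndices(aciniXY[j, 1L], aciniXY[j, 2L], aR, w, h)
    lum <- discIndices(aciniXY[j, 1L], aciniXY[j, 2L], max(aR - 2.5, 1), w, h)
    cls[ring] <- 5L                       # epithelial ring
    cls[lum] <- 6L                        # lumen
  }
  colmat <- rbind(pal$background, pal$stroma, pal$tdlu, pal$adipose,
                  pal$ring, pal$lumen)
  image <- array(0, dim = c(h, w, 3L))
  for (ch in 1:3) image[, , ch] <- matrix(colmat[cls, ch], h, w)

  truth <- SlideObservations(
    tissue = BinaryMask(frame, tissue),
    adipose = BinaryMask(frame, adipose),
    tdlus = LabelMask(frame, labels),
    acini = PointSet(frame, x = aciniXY[, 1L], y = aciniXY[, 2L]))

  ## true measures from planted geometry (areas from the raster so they are
  ## raster-consistent; spans are the planted diameters)
  adjArea <- adjustedTissueAreaMm2(tissueAreaMm2(truth@tissue),
                                   if (nTissue) sum(adipose) / nTissue else 0)
  if (K) {
    pxArea <- pixelAreaMm2(frame)
    instPx <- tabulate(labels[labels > 0L], nbins = K)
    rec <- data.frame(label = seq_len(K),
                      area_mm2 = instPx * pxArea,
                      span_um = 2 * tdluR * res,
                      acini_count_raw = aciniCounts,
                      acini_count_calibrated = as.numeric(aciniCounts),
                      centroid_x = centers[, 1L], centroid_y = centers[, 2L])
    trueMeasures <- MeasureSet(K, adjArea, K / adjArea,
                               stats::median(rec$span_um),
                               stats::median(rec$acini_count_raw),
                               nrow(aciniXY) / adjArea,
                               stats::median(rec$area_mm2))
  } else {
    rec <- data.frame(label = integer(), area_mm2 = numeric(),
                      span_um = numeric(), acini_count_raw = integer(),
                      acini_count_calibrated = numeric(),
                      centroid_x = numeric(), centroid_y = numeric())
    trueMeasures <- MeasureSet(0L, adjArea, 0, NA_real_, NA_real_, 0,
                               NA_real_)
  }
  trueTypes <- classifySlide(rec, useCalibrated = FALSE)

  new("SyntheticSlide", image = image, truth = truth,
      trueMeasures = trueMeasures, trueRecords = rec,
      trueTypes = trueTypes, spec = unclass(spec))
}

#' Perturb ground-truth acini detections
#'
#' Models an imperfect detector for evaluation studies: each true acinus is
#' dropped independently with probability \code{dropRate}; spurious
#' detections are added as a Poisson process with intensity
#' \code{spuriousPerMm2} over the tissue area (placed uniformly on tissue
#' pixels); surviving points are jittered by an isotropic Gaussian with
#' standard deviation \code{jitterUm} per axis (clamped to the frame).
#'
#' @param truth a \linkS4class{SlideObservations}
#' @param dropRate miss probability in [0, 1)
#' @param spuriousPerMm2 false-positive intensity per mm^2 of tissue
#' @param jitterUm localization noise SD in micrometres
#' @param seed RNG seed
#' @return a \linkS4class{SlideObservations} with perturbed acini
#' @export
perturbObservations <- function(truth, dropRate = 0, spuriousPerMm2 = 0,
                                jitterUm = 0, seed = 1L) {
  stopifnot(dropRate >= 0, dropRate < 1, spuriousPerMm2 >= 0, jitterUm >= 0)
  withSeed(seed, function() {
    frame <- truth@frame
    res <- frame@resolutionUmPerPx
    xy <- truth@acini@coords
    if (nrow(xy) && dropRate > 0)
      xy <- xy[stats::runif(nrow(xy)) >= dropRate, , drop = FALSE]
    if (nrow(xy) && jitterUm > 0) {
      xy <- xy + matrix(stats::rnorm(2L * nrow(xy), 0, jitterUm / res),
                        ncol = 2L)
      xy[, 1L] <- pmin(pmax(xy[, 1L], -0.499), frame@widthPx - 0.501)
      xy[, 2L] <- pmin(pmax(xy[, 2L], -0.499), frame@heightPx - 0.501)
    }
    if (spuriousPerMm2 > 0) {
      areaMm2 <- tissueAreaMm2(truth@tissue)
      nSpur <- stats::rpois(1L, spuriousPerMm2 * areaMm2)
      if (nSpur > 0L) {
        cand <- which(truth@tissue@pixels)
        pick <- cand[sample.int(length(cand), nSpur, replace = TRUE)]
        h <- frame@heightPx
        sx <- (pick - 1L) %/% h; sy <- (pick - 1L) %% h
        xy <- rbind(xy, cbind(sx + stats::runif(nSpur, -0.5, 0.5),
                              sy + stats::runif(nSpur, -0.5, 0.5)))
        xy[, 1L] <- pmin(pmax(xy[, 1L], -0.499), frame@widthPx - 0.501)
        xy[, 2L] <- pmin(pmax(xy[, 2L], -0.499), frame@heightPx - 0.501)
      }
    }
    SlideObservations(tissue = truth@tissue, adipose = truth@adipose,
                      tdlus = truth@tdlus,
                      acini = PointSet(frame, x = xy[, 1L], y = xy[, 2L]))
  })
}

#' Simulate a manual observer's slide assessment
#'
#' Emulates the manual protocol used to validate automated involution
#' measures: the observer selects a region of interest (ROI) of
#' approximately \code{roiAreaMm2}, estimates adipose content in the four
#' observer bins, counts the TDLUs in the ROI, and randomly selects up to
#' \code{maxTdlus} of them to measure span and count acini, with optional
#' multiplicative reading noise and a hidden counting-scale factor (used to
#' study calibration fitting). An ROI larger than the slide covers the
#' whole slide.
#'
#' @param truth ground-truth \linkS4class{SlideObservations}
#' @param roiAreaMm2 target ROI area (square ROI), mm^2
#' @param maxTdlus maximum TDLUs sampled for span/count reads
#' @param spanCV,countCV coefficient of variation of multiplicative reading
#'   noise on span and acini count (0 = exact reads)
#' @param countScale hidden factor applied to acini counts before rounding
#'   (an observer counting on a different scale than the detector)
#' @param seed RNG seed
#' @return list with \code{flagged} (TRUE when no TDLU fell in the ROI),
#'   \code{roi} (x0, y0, x1, y1 px), \code{adiposeBin}, \code{nTdlus},
#'   \code{tissueAreaMm2}, \code{adjustedAreaMm2} (bin-centre adjusted),
#'   \code{tdlusPerMm2}, \code{medianSpanUm}, \code{medianAciniPerTdlu} and
#'   \code{perTdlu} (sampled label, span_um, acini_count)
#' @export
simulateObserver <- function(truth, roiAreaMm2 = 50, maxTdlus = 10,
                             spanCV = 0, countCV = 0, countScale = 1,
                             seed = 1L) {
  withSeed(seed, function() {
    frame <- truth@frame
    res <- frame@resolutionUmPerPx
    sidePx <- sqrt(roiAreaMm2) * 1000 / res
    w <- frame@widthPx; h <- frame@heightPx
    sideX <- min(sidePx, w); sideY <- min(sidePx, h)
    x0 <- if (w - sideX > 0) stats::runif(1, 0, w - sideX) else 0
    y0 <- if (h - sideY > 0) stats::runif(1, 0, h - sideY) else 0
    roi <- c(x0 = x0, y0 = y0, x1 = x0 + sideX, y1 = y0 + sideY)

    cols <- max(1L, ceiling(x0 + 0.5)):min(w, floor(roi["x1"] + 0.5))
    rows <- max(1L, ceiling(y0 + 0.5)):min(h, floor(roi["y1"] + 0.5))
    tIn <- truth@tissue@pixels[rows, cols, drop = FALSE]
    tissueArea <- sum(tIn) * pixelAreaMm2(frame)

    trueFrac <- if (is(truth@adipose, "BinaryMask")) {
      aIn <- truth@adipose@pixels[rows, cols, drop = FALSE]
      if (sum(tIn)) sum(aIn & tIn) / sum(tIn) else 0
    } else adiposeFraction(truth@adipose)
    bin <- c("<25%", "25-50%", "50-75%", ">75%")[
      findInterval(trueFrac, c(0.25, 0.50, 0.75)) + 1L]
    adjArea <- adjustedTissueAreaMm2(tissueArea, adiposeBinCenter(bin))

    inst <- instanceCoords(truth@tdlus)
    inRoi <- vapply(inst, function(m) {
      cx <- mean(m[, 1L]); cy <- mean(m[, 2L])
      cx >= roi["x0"] && cx <= roi["x1"] && cy >= roi["y0"] && cy <= roi["y1"]
    }, logical(1))
    labs <- as.integer(names(inst))[inRoi]
    nT <- length(labs)

    if (nT == 0L) {
      return(list(flagged = TRUE, roi = roi, adiposeBin = bin,
                  nTdlus = 0L, tissueAreaMm2 = tissueArea,
                  adjustedAreaMm2 = adjArea,
                  tdlusPerMm2 = if (adjArea > 0) 0 else NA_real_,
                  medianSpanUm = NA_real_, medianAciniPerTdlu = NA_real_,
                  perTdlu = data.frame(label = integer(),
                                       span_um = numeric(),
                                       acini_count = numeric())))
    }

    sampled <- if (nT > maxTdlus) sort(sample(labs, maxTdlus)) else labs
    asg <- assignAcini(truth@acini, truth@tdlus)
    spans <- vapply(inst[as.character(sampled)],
                    function(m) tdluSpanUm(m, frame), numeric(1))
    counts <- as.numeric(asg$counts[as.character(sampled)])
    if (spanCV > 0)
      spans <- spans * pmax(stats::rnorm(length(spans), 1, spanCV), 0.05)
    counts <- counts * countScale
    if (countCV > 0)
      counts <- counts * pmax(stats::rnorm(length(counts), 1, countCV), 0.05)
    if (countScale != 1 || countCV > 0)
      counts <- pmax(round(counts), 1)

    list(flagged = FALSE, roi = roi, adiposeBin = bin,
         nTdlus = nT, tissueAreaMm2 = tissueArea,
         adjustedAreaMm2 = adjArea,
         tdlusPerMm2 = nT / adjArea,
         medianSpanUm = stats::median(spans),
         medianAciniPerTdlu = stats::median(counts),
         perTdlu = data.frame(label = sampled, span_um = unname(spans),
                              acini_count = unname(counts)))
  })
}
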