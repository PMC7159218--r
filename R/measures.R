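#' @include slideModel.R
NULL

#' Tissue area in square millimetres
#'
#' Foreground pixel count times the per-pixel area of the frame.
#'
#' @param tissue a \linkS4class{BinaryMask}
#' @return area in mm^2
#' @export
tissueAreaMm2 <- function(tissue) {
  stopifnot(is(tissue, "BinaryMask"))
  sum(tissue@pixels) * pixelAreaMm2(tissue@frame)
}

adiposeBinCenter <- function(bin) {
  centers <- c("<25%" = 0.125, "25-50%" = 0.375, "50-75%" = 0.625,
               ">75%" = 0.875)
  unname(centers[bin])
}

#' Adipose fraction of the tissue
#'
#' Reduces any adipose representation to a fraction in [0, 1]:
#' \itemize{
#'   \item mask: |adipose AND tissue| / |tissue|
#'   \item observer bin: the bin centre (12.5, 37.5, 62.5 or 87.5 per cent),
#'     the convention used when manual categorical estimates enter the
#'     adjusted-area computation
#'   \item fraction: identity
#' }
#'
#' @param adipose a \linkS4class{BinaryMask} or \linkS4class{AdiposeEstimate}
#' @param tissue the tissue \linkS4class{BinaryMask}; required in mask mode
#' @return adipose fraction in [0, 1]
#' @export
adiposeFraction <- function(adipose, tissue = NULL) {
  if (is(adipose, "AdiposeEstimate")) {
    if (adipose@mode == "fraction") return(adipose@fraction)
    return(adiposeBinCenter(adipose@bin))
  }
  stopifnot(is(adipose, "BinaryMask"), is(tissue, "BinaryMask"))
  if (!sameFrame(adipose@frame, tissue@frame))
    stop("adipose and tissue masks must share a frame")
  nTissue <- sum(tissue@pixels)
  if (nTissue == 0L)
    stop("adipose fraction undefined: tissue mask is empty")
  sum(adipose@pixels & tissue@pixels) / nTissue
}

#' Adipose-adjusted tissue area
#'
#' Multiplies the total tissue area by the non-adipose percentage, so that
#' densities are expressed per unit of epithelial-stromal tissue.
#'
#' @param areaMm2 total tissue area, mm^2
#' @param adiposeFrac adipose fraction in [0, 1]
#' @return adjusted area in mm^2: areaMm2 * (1 - adiposeFrac)
#' @export
adjustedTissueAreaMm2 <- function(areaMm2, adiposeFrac) {
  if (is.na(adiposeFrac) || adiposeFrac < 0 || adiposeFrac > 1)
    stop("adiposeFrac must be in [0, 1]")
  areaMm2 * (1 - adiposeFrac)
}

# Largest eigenvalue of the 2x2 population covariance of (x, y) coords.
covMajorEigen <- function(xy) {
  n <- nrow(xy)
  mx <- mean(xy[, 1L]); my <- mean(xy[, 2L])
  dx <- xy[, 1L] - mx; dy <- xy[, 2L] - my
  a <- sum(dx * dx) / n; b <- sum(dy * dy) / n; c <- sum(dx * dy) / n
  (a + b) / 2 + sqrt(((a - b) / 2)^2 + c^2)
}

#' TDLU span from second central moments
#'
#' The span of a TDLU instance is the length of the major axis of the
#' ellipse with the same normalized second central moments as the region:
#' 4 * sqrt(lambda_max) pixels, where lambda_max is the largest eigenvalue
#' of the population covariance matrix of the instance's pixel-centre
#' coordinates, converted to micrometres by the frame resolution. No
#' pixel-extent variance correction is applied; for regions more than a few
#' pixels across the difference is below one pixel.
#'
#' For a filled disc of radius r the coordinate variance along any axis is
#' r^2/4, so the span equals the diameter 2r (up to rasterization error).
#' A single pixel has zero covariance and span 0.
#'
#' @param xy numeric matrix of instance pixel coordinates, columns (x, y)
#'   in pixels (0-based pixel centres)
#' @param frame the \linkS4class{SlideFrame} supplying the resolution
#' @return span in micrometres
#' @export
tdluSpanUm <- function(xy, frame) {
  if (is.null(dim(xy)) || nrow(xy) == 0L)
    stop("empty instance: span undefined")
  4 * sqrt(covMajorEigen(xy)) * frame@resolutionUmPerPx
}

#' TDLU area from its pixel set
#'
#' @param xy matrix of instance pixel coordinates (one row per pixel)
#' @param frame the \linkS4class{SlideFrame}
#' @return area in mm^2 (pixel count times per-pixel area)
#' @export
tdluAreaMm2 <- function(xy, frame) {
  if (is.null(dim(xy)) || nrow(xy) == 0L)
    stop("empty instance: area undefined")
  nrow(xy) * pixelAreaMm2(frame)
}

#' Extract TDLU instances from a semantic mask
#'
#' Converts a semantic (binary) TDLU segmentation into instance labels via
#' 4-connected components, the rule used when a segmentation backend emits
#' only a foreground mask.
#'
#' @param mask a \linkS4class{BinaryMask}
#' @return a \linkS4class{LabelMask} with gapless labels 1..K
#' @export
labelInstances <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  lab <- EBImage::bwlabel(t(mask@pixels) * 1)   # EBImage is (x, y)-ordered
  LabelMask(mask@frame, t(matrix(as.integer(lab), nrow(lab), ncol(lab))))
}

# Per-instance pixel coordinates: list (by label 1..K) of (x, y) matrices.
instanceCoords <- function(tdlus) {
  labs <- tdlus@labels
  idx <- which(labs > 0L)
  if (!length(idx))
    return(list())
  rc <- arrayInd(idx, dim(labs))
  xy <- cbind(x = rc[, 2L] - 1, y = rc[, 1L] - 1)
  split.data.frame(xy, labs[idx])
}

#' Assign acini detections to TDLU instances
#'
#' Each acinus is assigned to the instance label of the pixel containing
#' its centroid (centroid containment; no nearest-TDLU snapping). Points on
#' background pixels are unassigned.
#'
#' @param acini a \linkS4class{PointSet}
#' @param tdlus a \linkS4class{LabelMask} sharing the frame
#' @return list with \code{counts} (named integer vector over labels 1..K)
#'   and \code{nUnassigned}; counts + nUnassigned = number of points
#' @export
assignAcini <- function(acini, tdlus) {
  if (!sameFrame(acini@frame, tdlus@frame))
    stop("acini and tdlus must share a frame")
  K <- max(tdlus@labels, 0L)
  counts <- integer(K)
  names(counts) <- if (K) as.character(seq_len(K)) else character()
  xy <- acini@coords
  if (!nrow(xy))
    return(list(counts = counts, nUnassigned = 0L))
  col <- pmin(pmax(floor(xy[, 1L] + 0.5), 0), tdlus@frame@widthPx - 1L) + 1L
  row <- pmin(pmax(floor(xy[, 2L] + 0.5), 0), tdlus@frame@heightPx - 1L) + 1L
  lab <- tdlus@labels[cbind(row, col)]
  tab <- table(factor(lab[lab > 0L], levels = seq_len(K)))
  counts[] <- as.integer(tab)
  list(counts = counts, nUnassigned = sum(lab == 0L))
}

#' Default calibration model
#'
#' @param coefficient multiplicative factor mapping automated acini-per-TDLU
#'   counts onto the manual counting scale; the published default is 3.888
#' @return a \linkS4class{CalibrationModel} with source "paper_default"
#' @export
defaultCalibration <- function(coefficient = 3.888) {
  new("CalibrationModel", coefficient = as.numeric(coefficient),
      intercept = 0, nPairs = 0L, source = "paper_default",
      interceptEstimate = NA_real_, interceptSE = NA_real_)
}

#' Apply a calibration model to an acini count
#'
#' @param countRaw raw automated count (>= 0)
#' @param model a \linkS4class{CalibrationModel}
#' @return countRaw * coefficient
#' @export
calibrate <- function(countRaw, model = defaultCalibration()) {
  stopifnot(all(countRaw >= 0, na.rm = TRUE))
  countRaw * model@coefficient
}

#' Fit a calibration model by regression through the origin
#'
#' Least-squares regression of manual on automated counts with the
#' intercept fixed at zero: coefficient = sum(auto * manual) / sum(auto^2).
#' The free-intercept fit is also run and its intercept estimate and
#' standard error are stored as diagnostics, supporting the origin
#' constraint when the intercept is not significantly different from zero.
#'
#' @param auto automated acini-per-TDLU values (>= 2, not all zero)
#' @param manual paired manual values, same length
#' @return a \linkS4class{CalibrationModel} with source "fitted"
#' @export
fitCalibration <- function(auto, manual) {
  auto <- as.numeric(auto); manual <- as.numeric(manual)
  if (length(auto) != length(manual))
    stop("auto and manual must have equal length")
  if (length(auto) < 2L)
    stop("need at least 2 calibration pairs")
  if (all(auto == 0))
    stop("degenerate design: all automated values are zero")
  coef <- sum(auto * manual) / sum(auto^2)
  intEst <- NA_real_; intSE <- NA_real_
  if (length(auto) >= 3L && stats::var(auto) > 0) {
    free <- stats::lm(manual ~ auto)
    sm <- suppressWarnings(summary(free))$coefficients  # noiseless fits warn
    intEst <- sm["(Intercept)", "Estimate"]
    intSE <- sm["(Intercept)", "Std. Error"]
  }
  new("CalibrationModel", coefficient = coef, intercept = 0,
      nPairs = length(auto), source = "fitted",
      interceptEstimate = intEst, interceptSE = intSE)
}

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf("CalibrationModel (%s): calibrated = %.4f * raw\n",
              object@source, object@coefficient))
  if (object@source == "fitted") {
    cat(sprintf("  n pairs: %d\n", object@nPairs))
    if (!is.na(object@interceptEstimate))
      cat(sprintf("  free-intercept diagnostic: %.4f (SE %.4f)\n",
                  object@interceptEstimate, object@interceptSE))
  }
})

#' Construct a MeasureSet
#'
#' Usually produced by \code{\link{computeMeasures}}; direct construction is
#' available for tests and for reading measure tables back in.
#'
#' @param nTdlus,adjustedTissueAreaMm2,tdlusPerMm2,medianSpanUm
#'   slide-level measures; see \linkS4class{MeasureSet}
#' @param medianAciniPerTdlu,aciniPerMm2,medianTdluAreaMm2 remaining measures
#' @return a \linkS4class{MeasureSet}
#' @export
MeasureSet <- function(nTdlus, adjustedTissueAreaMm2, tdlusPerMm2,
                       medianSpanUm, medianAciniPerTdlu, aciniPerMm2,
                       medianTdluAreaMm2) {
  new("MeasureSet", nTdlus = as.integer(nTdlus),
      adjustedTissueAreaMm2 = as.numeric(adjustedTissueAreaMm2),
      tdlusPerMm2 = as.numeric(tdlusPerMm2),
      medianSpanUm = as.numeric(medianSpanUm),
      medianAciniPerTdlu = as.numeric(medianAciniPerTdlu),
      aciniPerMm2 = as.numeric(aciniPerMm2),
      medianTdluAreaMm2 = as.numeric(medianTdluAreaMm2))
}

#' @export
#' @method as.data.frame MeasureSet
as.data.frame.MeasureSet <- function(x, ...) {
  data.frame(n_tdlus = x@nTdlus,
             adjusted_tissue_area_mm2 = x@adjustedTissueAreaMm2,
             tdlus_per_mm2 = x@tdlusPerMm2,
             median_span_um = x@medianSpanUm,
             median_acini_per_tdlu = x@medianAciniPerTdlu,
             acini_per_mm2 = x@aciniPerMm2,
             median_tdlu_area_mm2 = x@medianTdluAreaMm2)
}

setMethod("show", "MeasureSet", function(object) {
  cat("MeasureSet\n")
  df <- as.data.frame.MeasureSet(object)
  for (nm in names(df)) cat(sprintf("  %-26s %s\n", nm, format(df[[nm]])))
})

#' Compute the five quantitative involution measures for one slide
#'
#' Runs the full quantitative pipeline on a set of slide observations:
#' \enumerate{
#'   \item tissue area, adipose fraction and adipose-adjusted tissue area;
#'   \item per-TDLU area, moment-ellipse span and centroid, with instances
#'     below \code{minTdluAreaMm2} excluded before all statistics;
#'   \item acini assigned to TDLUs by centroid containment;
#'   \item slide-level measures: TDLUs/mm^2, median span (um), median
#'     acini/TDLU (median of raw counts, then calibrated), acini/mm^2
#'     (all detections, including those outside TDLUs) and median TDLU
#'     area (mm^2).
#' }
#' Medians are NA (with a warning) when no TDLU is retained. The median of
#' an even number of values is the mean of the two central order statistics.
#' Calibration is applied to the median of the raw counts; by linearity this
#' equals the median of per-TDLU calibrated counts.
#'
#' @param obs a valid \linkS4class{SlideObservations}
#' @param model a \linkS4class{CalibrationModel}
#' @param minTdluAreaMm2 exclude instances with area below this (default 0,
#'   i.e. no size filter)
#' @return list with \code{measures} (a \linkS4class{MeasureSet}) and
#'   \code{records} (per-TDLU data.frame: label, area_mm2, span_um,
#'   acini_count_raw, acini_count_calibrated, centroid_x, centroid_y)
#' @export
computeMeasures <- function(obs, model = defaultCalibration(),
                            minTdluAreaMm2 = 0) {
  viol <- validateObservations(obs)
  if (length(viol))
    stop("invalid observations: ", paste(viol, collapse = "; "))
  frame <- obs@frame
  area <- tissueAreaMm2(obs@tissue)
  frac <- adiposeFraction(obs@adipose, obs@tissue)
  adjArea <- adjustedTissueAreaMm2(area, frac)
  if (adjArea <= 0)
    stop("adjusted tissue area is zero: densities undefined")

  inst <- instanceCoords(obs@tdlus)
  asg <- assignAcini(obs@acini, obs@tdlus)

  records <- data.frame(label = integer(), area_mm2 = numeric(),
                        span_um = numeric(), acini_count_raw = integer(),
                        acini_count_calibrated = numeric(),
                        centroid_x = numeric(), centroid_y = numeric())
  if (length(inst)) {
    labels <- as.integer(names(inst))
    areas <- vapply(inst, function(m) tdluAreaMm2(m, frame), numeric(1))
    spans <- vapply(inst, function(m) tdluSpanUm(m, frame), numeric(1))
    cx <- vapply(inst, function(m) mean(m[, 1L]), numeric(1))
    cy <- vapply(inst, function(m) mean(m[, 2L]), numeric(1))
    raw <- as.integer(asg$counts[as.character(labels)])
    records <- data.frame(label = labels, area_mm2 = unname(areas),
                          span_um = unname(spans),
                          acini_count_raw = raw,
                          acini_count_calibrated = calibrate(raw, model),
                          centroid_x = unname(cx), centroid_y = unname(cy))
    keep <- records$area_mm2 >= minTdluAreaMm2
    records <- records[keep, , drop = FALSE]
  }

  n <- nrow(records)
  if (n == 0L) {
    warning("no TDLUs retained: median measures are undefined (NA)")
    ms <- MeasureSet(0L, adjArea, 0, NA_real_, NA_real_,
                     nrow(obs@acini@coords) / adjArea, NA_real_)
  } else {
    ms <- MeasureSet(n, adjArea,
                     n / adjArea,
                     stats::median(records$span_um),
                     calibrate(stats::median(records$acini_count_raw), model),
                     nrow(obs@acini@coords) / adjArea,
                     stats::median(records$area_mm2))
  }
  list(measures = ms, records = records)
}
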