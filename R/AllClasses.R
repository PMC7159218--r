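#' @import methods
NULL

#' SlideFrame: pixel grid geometry and physical resolution
#'
#' Ties pixel measurements to physical units. All rasters and point sets in a
#' slide share one frame. The default resolution of 0.16 micrometres per pixel
#' corresponds to a 40x whole-slide scan; synthetic slides typically use a
#' coarser resolution.
#'
#' Coordinate convention used throughout the package: points are 0-based
#' (x, y) with x rightward and y downward, the origin at the centre of the
#' top-left pixel; raster matrices are indexed (row = y + 1, col = x + 1).
#'
#' @slot widthPx frame width in pixels (>= 1)
#' @slot heightPx frame height in pixels (>= 1)
#' @slot resolutionUmPerPx physical size of one pixel in micrometres (> 0)
#' @exportClass SlideFrame
setClass("SlideFrame",
  representation(widthPx = "integer", heightPx = "integer",
                 resolutionUmPerPx = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@widthPx) != 1L || is.na(object@widthPx) ||
        object@widthPx < 1L)
      msg <- c(msg, "widthPx must be a single integer >= 1")
    if (length(object@heightPx) != 1L || is.na(object@heightPx) ||
        object@heightPx < 1L)
      msg <- c(msg, "heightPx must be a single integer >= 1")
    if (length(object@resolutionUmPerPx) != 1L ||
        is.na(object@resolutionUmPerPx) || object@resolutionUmPerPx <= 0)
      msg <- c(msg, "resolutionUmPerPx must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' BinaryMask: a boolean raster tied to a SlideFrame
#'
#' Houses tissue-foreground and adipose masks. The pixel matrix has
#' dimensions (heightPx, widthPx) of its frame.
#'
#' @slot frame a \linkS4class{SlideFrame}
#' @slot pixels logical matrix, dim = c(heightPx, widthPx)
#' @exportClass BinaryMask
setClass("BinaryMask",
  representation(frame = "SlideFrame", pixels = "matrix"),
  validity = function(object) {
    msg <- character()
    if (!is.logical(object@pixels))
      msg <- c(msg, "pixels must be a logical matrix")
    if (nrow(object@pixels) != object@frame@heightPx ||
        ncol(object@pixels) != object@frame@widthPx)
      msg <- c(msg, "pixels dimensions must equal frame (heightPx, widthPx)")
    if (anyNA(object@pixels))
      msg <- c(msg, "pixels must not contain NA")
    if (length(msg)) msg else TRUE
  })

#' LabelMask: TDLU instance labels as a non-negative integer raster
#'
#' 0 is background; k >= 1 identifies TDLU instance k. After
#' \code{\link{normalizeLabels}} the label set is \{0\} followed by a gapless
#' 1..K, every instance nonempty.
#'
#' @slot frame a \linkS4class{SlideFrame}
#' @slot labels integer matrix, dim = c(heightPx, widthPx), values >= 0
#' @exportClass LabelMask
setClass("LabelMask",
  representation(frame = "SlideFrame", labels = "matrix"),
  validity = function(object) {
    msg <- character()
    if (!is.integer(object@labels))
      msg <- c(msg, "labels must be an integer matrix")
    if (nrow(object@labels) != object@frame@heightPx ||
        ncol(object@labels) != object@frame@widthPx)
      msg <- c(msg, "labels dimensions must equal frame (heightPx, widthPx)")
    if (anyNA(object@labels) || (length(object@labels) && min(object@labels) < 0L))
      msg <- c(msg, "labels must be non-negative integers without NA")
    if (length(msg)) msg else TRUE
  })

#' PointSet: acini detections as sub-pixel point coordinates
#'
#' Points are (x, y) in pixel units, 0-based, origin at the top-left pixel
#' centre. All points must lie inside the frame: -0.5 <= x < widthPx - 0.5
#' and likewise for y (the frame covers pixel extents, not just centres).
#'
#' @slot frame a \linkS4class{SlideFrame}
#' @slot coords numeric matrix with columns x, y (possibly 0 rows)
#' @exportClass PointSet
setClass("PointSet",
  representation(frame = "SlideFrame", coords = "matrix"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@coords) || ncol(object@coords) != 2L)
      msg <- c(msg, "coords must be a numeric matrix with 2 columns (x, y)")
    else {
      if (anyNA(object@coords))
        msg <- c(msg, "coords must not contain NA")
      else if (nrow(object@coords)) {
        x <- object@coords[, 1L]; y <- object@coords[, 2L]
        if (any(x < -0.5 | x >= object@frame@widthPx - 0.5) ||
            any(y < -0.5 | y >= object@frame@heightPx - 0.5))
          msg <- c(msg, "PointSet coords out of frame bounds")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' AdiposeEstimate: adipose content as a fraction or an observer bin
#'
#' The automated path measures adipose as a mask (see
#' \linkS4class{SlideObservations}); the manual-observer path records one of
#' four bins. Bins reduce to their centre values 12.5, 37.5, 62.5 and 87.5
#' per cent when an adipose fraction is needed.
#'
#' @slot mode "fraction" or "bin"
#' @slot fraction adipose fraction in [0, 1] (mode = "fraction"; NA otherwise)
#' @slot bin one of "<25%", "25-50%", "50-75%", ">75%" (mode = "bin")
#' @exportClass AdiposeEstimate
setClass("AdiposeEstimate",
  representation(mode = "character", fraction = "numeric", bin = "character"),
  validity = function(object) {
    bins <- c("<25%", "25-50%", "50-75%", ">75%")
    if (!object@mode %in% c("fraction", "bin"))
      return("mode must be 'fraction' or 'bin'")
    if (object@mode == "fraction") {
      if (is.na(object@fraction) || object@fraction < 0 || object@fraction > 1)
        return("fraction must be in [0, 1] when mode = 'fraction'")
      if (!is.na(object@bin))
        return("bin must be NA when mode = 'fraction'")
    } else {
      if (is.na(object@bin) || !object@bin %in% bins)
        return(paste("bin must be one of", paste(bins, collapse = ", ")))
      if (!is.na(object@fraction))
        return("fraction must be NA when mode = 'bin'")
    }
    TRUE
  })

#' SlideObservations: everything measured on one slide
#'
#' The integration point of the pipeline: tissue-foreground mask, adipose
#' estimate (mask or observer bin), TDLU instance labels and acini point
#' detections, all sharing one \linkS4class{SlideFrame}.
#'
#' @slot frame a \linkS4class{SlideFrame}
#' @slot tissue \linkS4class{BinaryMask}
#' @slot adipose \linkS4class{BinaryMask} or \linkS4class{AdiposeEstimate}
#' @slot tdlus \linkS4class{LabelMask}
#' @slot acini \linkS4class{PointSet}
#' @exportClass SlideObservations
setClass("SlideObservations",
  representation(frame = "SlideFrame", tissue = "BinaryMask",
                 adipose = "ANY", tdlus = "LabelMask", acini = "PointSet"),
  validity = function(object) {
    if (!(is(object@adipose, "BinaryMask") || is(object@adipose, "AdiposeEstimate")))
      return("adipose must be a BinaryMask or an AdiposeEstimate")
    TRUE
  })

#' MeasureSet: the five quantitative involution measures for one slide
#'
#' Densities are counts divided by the adipose-adjusted tissue area; median
#' fields are NA exactly when the slide has no TDLUs. medianAciniPerTdlu is
#' on the calibrated (manual-equivalent) scale.
#'
#' @slot nTdlus number of TDLU instances retained
#' @slot adjustedTissueAreaMm2 tissue area times (1 - adipose fraction), mm^2
#' @slot tdlusPerMm2 TDLU density per adjusted mm^2
#' @slot medianSpanUm median moment-ellipse span, micrometres (NA if no TDLUs)
#' @slot medianAciniPerTdlu calibrated median acini per TDLU (NA if no TDLUs)
#' @slot aciniPerMm2 acini density per adjusted mm^2 (all detections)
#' @slot medianTdluAreaMm2 median TDLU area in mm^2 (NA if no TDLUs)
#' @exportClass MeasureSet
setClass("MeasureSet",
  representation(nTdlus = "integer", adjustedTissueAreaMm2 = "numeric",
                 tdlusPerMm2 = "numeric", medianSpanUm = "numeric",
                 medianAciniPerTdlu = "numeric", aciniPerMm2 = "numeric",
                 medianTdluAreaMm2 = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@nTdlus < 0L) msg <- c(msg, "nTdlus must be >= 0")
    if (!is.na(object@adjustedTissueAreaMm2) && object@adjustedTissueAreaMm2 < 0)
      msg <- c(msg, "adjustedTissueAreaMm2 must be >= 0")
    medNA <- c(is.na(object@medianSpanUm), is.na(object@medianAciniPerTdlu),
               is.na(object@medianTdluAreaMm2))
    if (object@nTdlus == 0L && !all(medNA))
      msg <- c(msg, "median fields must be NA when nTdlus = 0")
    if (object@nTdlus > 0L && any(medNA))
      msg <- c(msg, "median fields must be defined when nTdlus > 0")
    if (length(msg)) msg else TRUE
  })

#' QualitativeResult: Russo lobule types and Baer category for one slide
#'
#' Russo types: 1 (< 12 acini/lobule), 2 (12--80), 3 (> 80), on the
#' calibrated counting scale. Baer categories group slides by their type-1 /
#' type-3 composition. Predominant type and Baer category are NA exactly
#' when the slide has no TDLUs.
#'
#' @slot perTdluTypes integer vector of types in \{1,2,3\}, one per TDLU
#' @slot predominantType modal type (ties broken to the higher type); NA if empty
#' @slot baerCategory "no_type1", "mixed" or "predominantly_type1_no_type3"; NA if empty
#' @slot countsByType named integer vector with counts of types 1, 2, 3
#' @exportClass QualitativeResult
setClass("QualitativeResult",
  representation(perTdluTypes = "integer", predominantType = "integer",
                 baerCategory = "character", countsByType = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@perTdluTypes) &&
        !all(object@perTdluTypes %in% 1:3))
      msg <- c(msg, "perTdluTypes must be in {1, 2, 3}")
    if (sum(object@countsByType) != length(object@perTdluTypes))
      msg <- c(msg, "countsByType must sum to the number of TDLUs")
    empty <- length(object@perTdluTypes) == 0L
    if (empty != is.na(object@predominantType) ||
        empty != is.na(object@baerCategory))
      msg <- c(msg, "predominantType/baerCategory NA iff no TDLUs")
    if (length(msg)) msg else TRUE
  })

#' CalibrationModel: maps automated acini-per-TDLU counts to the manual scale
#'
#' A regression-through-origin model: calibrated = coefficient * raw. The
#' intercept is fixed at zero; the free-intercept fit's estimate and
#' standard error are retained as diagnostics of that choice.
#'
#' @slot coefficient multiplicative calibration factor (> 0); default 3.888
#' @slot intercept always 0
#' @slot nPairs number of (automated, manual) pairs behind a fitted model
#' @slot source "paper_default" or "fitted"
#' @slot interceptEstimate free-intercept fit's intercept (NA for default model)
#' @slot interceptSE its standard error (NA for default model)
#' @exportClass CalibrationModel
setClass("CalibrationModel",
  representation(coefficient = "numeric", intercept = "numeric",
                 nPairs = "integer", source = "character",
                 interceptEstimate = "numeric", interceptSE = "numeric"),
  validity = function(object) {
    msg <- character()
    if (is.na(object@coefficient) || object@coefficient <= 0)
      msg <- c(msg, "coefficient must be > 0")
    if (object@intercept != 0)
      msg <- c(msg, "intercept is fixed at 0")
    if (!object@source %in% c("paper_default", "fitted"))
      msg <- c(msg, "source must be 'paper_default' or 'fitted'")
    if (length(msg)) msg else TRUE
  })

#' MatchResult: one-to-one point-detection matching summary
#'
#' @slot tp,fp,fn true/false positives and false negatives
#' @slot pairs integer matrix (tp rows) of matched (pred, gt) indices
#' @slot precision tp / (tp + fp), 0 when the denominator is 0
#' @slot recall tp / (tp + fn), 0 when the denominator is 0
#' @slot f1 harmonic mean of precision and recall, 0 when both are 0
#' @exportClass MatchResult
setClass("MatchResult",
  representation(tp = "integer", fp = "integer", fn = "integer",
                 pairs = "matrix", precision = "numeric", recall = "numeric",
                 f1 = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@tp != nrow(object@pairs))
      msg <- c(msg, "tp must equal the number of matched pairs")
    if (any(c(object@tp, object@fp, object@fn) < 0L))
      msg <- c(msg, "tp, fp, fn must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' AgreementResult: an agreement statistic with its design metadata
#'
#' Holds either an ICC(3,1) (with 95% confidence interval) or a Fleiss'
#' kappa (with large-sample p-value against kappa = 0).
#'
#' @slot statistic the agreement coefficient
#' @slot ciLow,ciHigh 95% CI bounds (ICC; NA for kappa)
#' @slot pValue large-sample p-value (kappa; NA for ICC)
#' @slot method "icc_3_1" or "fleiss_kappa"
#' @slot nSubjects,nRaters design dimensions
#' @exportClass AgreementResult
setClass("AgreementResult",
  representation(statistic = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 pValue = "numeric", method = "character",
                 nSubjects = "integer", nRaters = "integer"),
  validity = function(object) {
    if (!object@method %in% c("icc_3_1", "fleiss_kappa"))
      return("method must be 'icc_3_1' or 'fleiss_kappa'")
    if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
        !(object@ciLow <= object@statistic + 1e-12 &&
          object@statistic <= object@ciHigh + 1e-12))
      return("ciLow <= statistic <= ciHigh must hold")
    TRUE
  })
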