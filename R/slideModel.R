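#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a SlideFrame
#'
#' @param widthPx,heightPx frame dimensions in pixels
#' @param resolutionUmPerPx micrometres per pixel; 0.16 corresponds to a 40x
#'   whole-slide scan
#' @return a \linkS4class{SlideFrame}
#' @examples
#' fr <- SlideFrame(1024, 768, 0.16)
#' pixelAreaMm2(fr)   # (0.16 / 1000)^2
#' @export
SlideFrame <- function(widthPx, heightPx, resolutionUmPerPx = 0.16) {
  new("SlideFrame", widthPx = as.integer(widthPx),
      heightPx = as.integer(heightPx),
      resolutionUmPerPx = as.numeric(resolutionUmPerPx))
}

#' Frame geometry accessors
#'
#' \code{pixelAreaMm2} converts one pixel to physical area:
#' (resolution / 1000)^2 square millimetres.
#'
#' @param x a \linkS4class{SlideFrame}
#' @return integer dimensions, resolution, or the per-pixel area in mm^2
#' @name SlideFrame-accessors
NULL

#' @rdname SlideFrame-accessors
#' @export
setMethod("widthPx", "SlideFrame", function(x) x@widthPx)
#' @rdname SlideFrame-accessors
#' @export
setMethod("heightPx", "SlideFrame", function(x) x@heightPx)
#' @rdname SlideFrame-accessors
#' @export
setMethod("resolutionUmPerPx", "SlideFrame", function(x) x@resolutionUmPerPx)
#' @rdname SlideFrame-accessors
#' @export
setMethod("pixelAreaMm2", "SlideFrame",
          function(x) (x@resolutionUmPerPx / 1000)^2)

setMethod("show", "SlideFrame", function(object) {
  cat(sprintf("SlideFrame %d x %d px @ %g um/px (%.3f x %.3f mm)\n",
              object@widthPx, object@heightPx, object@resolutionUmPerPx,
              object@widthPx * object@resolutionUmPerPx / 1000,
              object@heightPx * object@resolutionUmPerPx / 1000))
})

sameFrame <- function(a, b) {
  a@widthPx == b@widthPx && a@heightPx == b@heightPx &&
    isTRUE(all.equal(a@resolutionUmPerPx, b@resolutionUmPerPx))
}

#' Construct a BinaryMask
#'
#' @param frame a \linkS4class{SlideFrame}
#' @param pixels logical matrix of dim (heightPx, widthPx); a numeric matrix
#'   is thresholded at > 0
#' @return a \linkS4class{BinaryMask}
#' @export
BinaryMask <- function(frame, pixels) {
  if (!is.logical(pixels)) pixels <- pixels > 0
  new("BinaryMask", frame = frame, pixels = pixels)
}

#' Construct a LabelMask
#'
#' @param frame a \linkS4class{SlideFrame}
#' @param labels non-negative integer matrix of dim (heightPx, widthPx);
#'   0 is background
#' @return a \linkS4class{LabelMask}
#' @export
LabelMask <- function(frame, labels) {
  storage.mode(labels) <- "integer"
  new("LabelMask", frame = frame, labels = labels)
}

#' Construct a PointSet
#'
#' @param frame a \linkS4class{SlideFrame}
#' @param x,y point coordinates in pixels (0-based, origin at the top-left
#'   pixel centre), or \code{x} a 2-column matrix/data.frame with columns x, y
#' @return a \linkS4class{PointSet}
#' @export
PointSet <- function(frame, x = numeric(), y = NULL) {
  if (is.null(y)) {
    m <- as.matrix(as.data.frame(x))
    if (length(m) == 0L) m <- matrix(numeric(), 0L, 2L)
  } else {
    m <- cbind(as.numeric(x), as.numeric(y))
  }
  colnames(m) <- c("x", "y")
  new("PointSet", frame = frame, coords = m)
}

#' @rdname slideFrame
#' @export
setMethod("slideFrame", "BinaryMask", function(x) x@frame)
#' @rdname slideFrame
#' @export
setMethod("slideFrame", "LabelMask", function(x) x@frame)
#' @rdname slideFrame
#' @export
setMethod("slideFrame", "PointSet", function(x) x@frame)
#' @rdname slideFrame
#' @export
setMethod("slideFrame", "SlideObservations", function(x) x@frame)

#' @rdname maskPixels
#' @export
setMethod("maskPixels", "BinaryMask", function(x) x@pixels)
#' @rdname maskPixels
#' @export
setMethod("maskPixels", "LabelMask", function(x) x@labels)

#' @rdname pointCoords
#' @export
setMethod("pointCoords", "PointSet", function(x) x@coords)

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask %d x %d px, %d foreground (%.1f%%)\n",
              object@frame@widthPx, object@frame@heightPx,
              sum(object@pixels),
              100 * mean(object@pixels)))
})

setMethod("show", "LabelMask", function(object) {
  k <- length(setdiff(unique(as.vector(object@labels)), 0L))
  cat(sprintf("LabelMask %d x %d px, %d instance(s)\n",
              object@frame@widthPx, object@frame@heightPx, k))
})

setMethod("show", "PointSet", function(object) {
  cat(sprintf("PointSet with %d point(s) in a %d x %d px frame\n",
              nrow(object@coords), object@frame@widthPx,
              object@frame@heightPx))
})

#' Construct an AdiposeEstimate
#'
#' @param fraction adipose fraction in [0, 1] (fraction mode)
#' @param bin observer bin, one of "<25%", "25-50%", "50-75%", ">75%"
#'   (bin mode); exactly one of \code{fraction} / \code{bin} must be given
#' @return an \linkS4class{AdiposeEstimate}
#' @export
AdiposeEstimate <- function(fraction = NULL, bin = NULL) {
  if (is.null(fraction) == is.null(bin))
    stop("supply exactly one of 'fraction' or 'bin'")
  if (!is.null(fraction))
    new("AdiposeEstimate", mode = "fraction",
        fraction = as.numeric(fraction), bin = NA_character_)
  else
    new("AdiposeEstimate", mode = "bin", fraction = NA_real_,
        bin = as.character(bin))
}

setMethod("show", "AdiposeEstimate", function(object) {
  if (object@mode == "fraction")
    cat(sprintf("AdiposeEstimate: fraction %.3f\n", object@fraction))
  else
    cat(sprintf("AdiposeEstimate: bin %s (centre %.3f)\n", object@bin,
                adiposeBinCenter(object@bin)))
})

#' Construct SlideObservations
#'
#' @param frame a \linkS4class{SlideFrame} (defaults to the tissue mask's)
#' @param tissue tissue-foreground \linkS4class{BinaryMask}
#' @param adipose a \linkS4class{BinaryMask} (automated path) or an
#'   \linkS4class{AdiposeEstimate} (manual-observer path)
#' @param tdlus TDLU \linkS4class{LabelMask}
#' @param acini acini \linkS4class{PointSet}
#' @return a \linkS4class{SlideObservations}
#' @export
SlideObservations <- function(tissue, adipose, tdlus, acini,
                              frame = slideFrame(tissue)) {
  new("SlideObservations", frame = frame, tissue = tissue,
      adipose = adipose, tdlus = tdlus, acini = acini)
}

setMethod("show", "SlideObservations", function(object) {
  cat("SlideObservations\n")
  cat("  "); show(object@frame)
  cat("  tissue:  "); show(object@tissue)
  cat("  adipose: ")
  if (is(object@adipose, "BinaryMask")) show(object@adipose)
  else show(object@adipose)
  cat("  tdlus:   "); show(object@tdlus)
  cat("  acini:   "); show(object@acini)
})

#' Validate a SlideObservations object
#'
#' A reporting operation: returns a character vector of violation
#' descriptions, empty when every invariant holds. Checked invariants:
#' all rasters share the observation frame; acini points lie in bounds;
#' label values are a gapless 1..K over nonempty instances; the adipose
#' estimate is well-formed.
#'
#' @param obs a \linkS4class{SlideObservations}
#' @return character vector of violations (length 0 when valid)
#' @export
validateObservations <- function(obs) {
  v <- character()
  if (!sameFrame(obs@frame, obs@tissue@frame))
    v <- c(v, "tissue: frame mismatch with observation frame")
  if (!sameFrame(obs@frame, obs@tdlus@frame))
    v <- c(v, "tdlus: frame mismatch with observation frame")
  if (!sameFrame(obs@frame, obs@acini@frame))
    v <- c(v, "acini: frame mismatch with observation frame")
  if (is(obs@adipose, "BinaryMask") && !sameFrame(obs@frame, obs@adipose@frame))
    v <- c(v, "adipose: frame mismatch with observation frame")

  xy <- obs@acini@coords
  if (nrow(xy)) {
    out <- xy[, 1L] < -0.5 | xy[, 1L] >= obs@frame@widthPx - 0.5 |
           xy[, 2L] < -0.5 | xy[, 2L] >= obs@frame@heightPx - 0.5
    if (any(out))
      v <- c(v, sprintf("acini: %d point(s) outside PointSet frame bounds",
                        sum(out)))
  }

  labs <- obs@tdlus@labels
  present <- sort(setdiff(unique(as.vector(labs)), 0L))
  if (length(present) && !identical(present, seq_along(present)))
    v <- c(v, "tdlus: label set has gaps; apply normalizeLabels()")
  v
}

#' Renumber TDLU instance labels to a gapless 1..K
#'
#' Keeps the order of first appearance by original label value; idempotent.
#'
#' @param mask a \linkS4class{LabelMask}
#' @return a \linkS4class{LabelMask} with labels \{0, 1, ..., K\}
#' @export
normalizeLabels <- function(mask) {
  labs <- mask@labels
  present <- sort(setdiff(unique(as.vector(labs)), 0L))
  if (identical(present, seq_along(present))) return(mask)
  lut <- integer(max(present) + 1L)           # lut[old + 1] = new
  lut[present + 1L] <- seq_along(present)
  out <- matrix(lut[labs + 1L], nrow(labs), ncol(labs))
  LabelMask(mask@frame, out)
}

#' Physical-unit helpers
#'
#' \code{pxToMm2} converts a pixel count to area in mm^2 for a frame;
#' \code{mm2ToPx} inverts it.
#'
#' @param nPixels pixel count
#' @param areaMm2 area in mm^2
#' @param frame a \linkS4class{SlideFrame}
#' @return area in mm^2, or pixel count
#' @export
pxToMm2 <- function(nPixels, frame) nPixels * pixelAreaMm2(frame)

#' @rdname pxToMm2
#' @export
mm2ToPx <- function(areaMm2, frame) areaMm2 / pixelAreaMm2(frame)
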