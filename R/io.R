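#' @include slideModel.R
NULL

#' AnnotationSet: polygon and point annotations for one slide
#'
#' The in-memory form of an annotation file: labelled polygons (TDLU /
#' adipose / tissue outlines) and labelled points (acinus markers). After
#' label mapping, labels are drawn from \{"acinus", "tdlu", "adipose",
#' "tissue"\}; unmapped labels are kept and reported, never silently
#' dropped.
#'
#' @slot polygons list of \code{list(label = chr, vertices = n x 2 matrix)}
#'   with >= 3 vertices each, pixel coordinates
#' @slot points data.frame with columns label, x, y (pixels)
#' @exportClass AnnotationSet
setClass("AnnotationSet",
  representation(polygons = "list", points = "data.frame"),
  validity = function(object) {
    bad <- vapply(object@polygons,
                  function(p) is.null(p$vertices) || nrow(p$vertices) < 3L,
                  logical(1))
    if (any(bad))
      return(sprintf("polygon(s) %s have fewer than 3 vertices",
                     paste(which(bad), collapse = ", ")))
    if (!all(c("label", "x", "y") %in% names(object@points)))
      return("points must have columns label, x, y")
    TRUE
  })

#' Construct an AnnotationSet
#'
#' @param polygons list of \code{list(label, vertices)} entries
#' @param points data.frame with columns label, x, y
#' @return an \linkS4class{AnnotationSet}
#' @export
AnnotationSet <- function(polygons = list(),
                          points = data.frame(label = character(),
                                              x = numeric(), y = numeric())) {
  new("AnnotationSet", polygons = polygons, points = points)
}

setMethod("show", "AnnotationSet", function(object) {
  cat(sprintf("AnnotationSet: %d polygon(s), %d point(s)\n",
              length(object@polygons), nrow(object@points)))
})

#' Read an ASAP-dialect annotation XML file
#'
#' Parses the Annotations/Annotation structure written by the ASAP slide
#' annotation tool: polygon-like annotations (Polygon, Rectangle, Spline)
#' become labelled polygons, Dot annotations become labelled points. The
#' annotation's group (\code{PartOfGroup}, falling back to \code{Name})
#' supplies the raw label, which is passed through \code{labelMap}; raw
#' labels missing from the map are kept as-is and reported in a warning.
#'
#' @param path XML file path
#' @param labelMap named character vector mapping raw labels to canonical
#'   labels ("acinus", "tdlu", "adipose", "tissue")
#' @return an \linkS4class{AnnotationSet}
#' @export
readAnnotationXML <- function(path, labelMap = c(acinus = "acinus",
                                                 tdlu = "tdlu",
                                                 adipose = "adipose",
                                                 tissue = "tissue")) {
  doc <- xml2::read_xml(path)   # malformed XML raises a parse error w/ line
  anns <- xml2::xml_find_all(doc, ".//Annotations/Annotation")
  polygons <- list()
  pts <- list()
  unmapped <- character()
  for (a in anns) {
    grp <- xml2::xml_attr(a, "PartOfGroup")
    raw <- if (!is.na(grp) && nzchar(grp) && grp != "None") grp
           else xml2::xml_attr(a, "Name")
    if (raw %in% names(labelMap)) lab <- unname(labelMap[[raw]])
    else { lab <- raw; unmapped <- c(unmapped, raw) }
    type <- xml2::xml_attr(a, "Type")
    coords <- xml2::xml_find_all(a, ".//Coordinates/Coordinate")
    ord <- as.numeric(xml2::xml_attr(coords, "Order"))
    x <- as.numeric(xml2::xml_attr(coords, "X"))[order(ord)]
    y <- as.numeric(xml2::xml_attr(coords, "Y"))[order(ord)]
    if (identical(type, "Dot")) {
      pts[[length(pts) + 1L]] <- data.frame(label = lab, x = x[1L],
                                            y = y[1L])
    } else {
      if (length(x) < 3L)
        stop(sprintf("annotation '%s' (%s) has %d vertices; polygons need >= 3",
                     xml2::xml_attr(a, "Name"), lab, length(x)))
      polygons[[length(polygons) + 1L]] <-
        list(label = lab, vertices = cbind(x = x, y = y))
    }
  }
  if (length(unmapped))
    warning("unmapped annotation label(s) kept as-is: ",
            paste(unique(unmapped), collapse = ", "))
  points <- if (length(pts)) do.call(rbind, pts)
            else data.frame(label = character(), x = numeric(), y = numeric())
  AnnotationSet(polygons = polygons, points = points)
}

#' Write an AnnotationSet as ASAP-dialect XML
#'
#' @param ann an \linkS4class{AnnotationSet}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeAnnotationXML <- function(ann, path) {
  doc <- xml2::xml_new_root("ASAP_Annotations")
  anns <- xml2::xml_add_child(doc, "Annotations")
  i <- 0L
  addCoords <- function(node, x, y) {
    cs <- xml2::xml_add_child(node, "Coordinates")
    for (j in seq_along(x))
      xml2::xml_add_child(cs, "Coordinate", Order = as.character(j - 1L),
                          X = format(x[j], digits = 12),
                          Y = format(y[j], digits = 12))
  }
  for (p in ann@polygons) {
    i <- i + 1L
    node <- xml2::xml_add_child(anns, "Annotation",
                                Name = sprintf("Annotation %d", i),
                                Type = "Polygon", PartOfGroup = p$label,
                                Color = "#F4FA58")
    addCoords(node, p$vertices[, 1L], p$vertices[, 2L])
  }
  for (j in seq_len(nrow(ann@points))) {
    i <- i + 1L
    node <- xml2::xml_add_child(anns, "Annotation",
                                Name = sprintf("Annotation %d", i),
                                Type = "Dot",
                                PartOfGroup = ann@points$label[j],
                                Color = "#F4FA58")
    addCoords(node, ann@points$x[j], ann@points$y[j])
  }
  groups <- xml2::xml_add_child(doc, "AnnotationGroups")
  for (g in unique(c(vapply(ann@polygons, `[[`, "", "label"),
                     ann@points$label)))
    xml2::xml_add_child(groups, "Group", Name = g, PartOfGroup = "None",
                        Color = "#F4FA58")
  xml2::write_xml(doc, path)
  invisible(path)
}

# Even-odd scanline fill: linear (column-major) indices of pixels whose
# centres lie inside (or on the boundary of) the polygon. Parity is
# evaluated just above and just below each scanline and OR-ed, so boundary
# rows/columns are included.
polygonIndices <- function(vertices, w, h) {
  vx <- vertices[, 1L]; vy <- vertices[, 2L]
  n <- length(vx)
  nxt <- c(2:n, 1L)
  out <- integer()
  y0 <- max(0L, floor(min(vy))); y1 <- min(h - 1L, ceiling(max(vy)))
  if (y1 < y0) return(out)
  eps <- 1e-7
  for (y in y0:y1) {
    cols <- logical(w)
    for (yy in c(y - eps, y + eps)) {
      cross <- (vy > yy) != (vy[nxt] > yy)
      if (!any(cross)) next
      xi <- vx[cross] + (yy - vy[cross]) *
        (vx[nxt][cross] - vx[cross]) / (vy[nxt][cross] - vy[cross])
      xi <- sort(xi)
      for (k in seq(1L, length(xi) - 1L, by = 2L)) {
        a <- ceiling(xi[k] - 1e-9); b <- floor(xi[k + 1L] + 1e-9)
        a <- max(a, 0L); b <- min(b, w - 1L)
        if (b >= a) cols[(a:b) + 1L] <- TRUE
      }
    }
    if (any(cols)) out <- c(out, (which(cols) - 1L) * h + y + 1L)
  }
  out
}

#' Rasterize annotations into slide observations
#'
#' Fills polygon interiors (even-odd rule, boundary-inclusive pixel
#' centres) into the frame: tissue and adipose polygons become binary
#' masks, each TDLU polygon becomes one instance label in drawing order,
#' and acinus points become a \linkS4class{PointSet}.
#'
#' @param ann an \linkS4class{AnnotationSet} (labels already canonical)
#' @param frame the target \linkS4class{SlideFrame}
#' @return list with elements \code{tissue}, \code{adipose}
#'   (\linkS4class{BinaryMask}), \code{tdlus} (\linkS4class{LabelMask}) and
#'   \code{acini} (\linkS4class{PointSet})
#' @export
rasterizeAnnotations <- function(ann, frame) {
  w <- frame@widthPx; h <- frame@heightPx
  bad <- which(vapply(ann@polygons, function(p)
    any(p$vertices[, 1L] < -0.5 | p$vertices[, 1L] >= w - 0.5 |
        p$vertices[, 2L] < -0.5 | p$vertices[, 2L] >= h - 0.5), logical(1)))
  if (length(bad))
    stop("polygon(s) with out-of-frame vertices: ",
         paste(bad, collapse = ", "))
  tissue <- matrix(FALSE, h, w)
  adipose <- matrix(FALSE, h, w)
  labels <- matrix(0L, h, w)
  k <- 0L
  for (p in ann@polygons) {
    idx <- polygonIndices(p$vertices, w, h)
    switch(p$label,
           tissue = { tissue[idx] <- TRUE },
           adipose = { adipose[idx] <- TRUE },
           tdlu = { k <- k + 1L; labels[idx] <- k })
  }
  ac <- ann@points[ann@points$label == "acinus", , drop = FALSE]
  list(tissue = BinaryMask(frame, tissue),
       adipose = BinaryMask(frame, adipose),
       tdlus = LabelMask(frame, labels),
       acini = PointSet(frame, x = ac$x, y = ac$y))
}

#' Write a mask as single-channel TIFF
#'
#' Binary masks are stored as 0/1, label masks as 16-bit instance labels
#' (instance counts can exceed the 8-bit range on dense slides). The
#' round-trip through \code{\link{readMask}} is lossless.
#'
#' @param mask a \linkS4class{BinaryMask} or \linkS4class{LabelMask}
#' @param path output .tif path
#' @return \code{path}, invisibly
#' @export
writeMask <- function(mask, path) {
  m <- if (is(mask, "BinaryMask")) mask@pixels * 1L else mask@labels
  if (max(m) > 65535L) stop("label values exceed 16-bit TIFF range")
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read a mask written by \code{\link{writeMask}}
#'
#' @param path single-channel image path (TIFF)
#' @param resolutionUmPerPx resolution to attach to the frame
#' @param as "auto" (binary when no value exceeds 1), "binary" or "label"
#' @return a \linkS4class{BinaryMask} or \linkS4class{LabelMask}
#' @export
readMask <- function(path, resolutionUmPerPx = 0.16,
                     as = c("auto", "binary", "label")) {
  as <- match.arg(as)
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L)
    stop("multi-channel image: masks must be single-channel")
  frame <- SlideFrame(ncol(m), nrow(m), resolutionUmPerPx)
  if (as == "binary" || (as == "auto" && max(m) <= 1L))
    BinaryMask(frame, m > 0L)
  else
    LabelMask(frame, matrix(as.integer(m), nrow(m), ncol(m)))
}

#' Read point detections from CSV
#'
#' Expects header columns \code{slide_id,x,y} with coordinates in pixels.
#'
#' @param path CSV path
#' @param frame the \linkS4class{SlideFrame} the points live in
#' @return a single \linkS4class{PointSet} when the file holds one slide,
#'   otherwise a named list of PointSets keyed by slide_id
#' @export
readPointsCSV <- function(path, frame) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("slide_id", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("points CSV missing required column(s): ",
         paste(miss, collapse = ", "))
  out <- lapply(split(df, df$slide_id),
                function(d) PointSet(frame, x = d$x, y = d$y))
  if (length(out) == 1L) out[[1L]] else out
}

#' Write point detections to CSV
#'
#' @param points a \linkS4class{PointSet} or named list of them
#' @param path output CSV path
#' @param slideId slide id for a single PointSet (default "slide1")
#' @return \code{path}, invisibly
#' @export
writePointsCSV <- function(points, path, slideId = "slide1") {
  if (is(points, "PointSet")) {
    points <- stats::setNames(list(points), slideId)
  }
  rows <- lapply(names(points), function(id) {
    xy <- points[[id]]@coords
    if (nrow(xy) == 0L)
      return(data.frame(slide_id = character(), x = numeric(),
                        y = numeric()))
    data.frame(slide_id = id, x = xy[, 1L], y = xy[, 2L])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read point detections from GeoJSON
#'
#' Accepts a FeatureCollection of Point features with pixel coordinates.
#'
#' @param path GeoJSON path
#' @param frame the \linkS4class{SlideFrame}
#' @return a \linkS4class{PointSet}
#' @export
readPointsGeoJSON <- function(path, frame) {
  g <- jsonlite::read_json(path)
  feats <- g$features
  pts <- vapply(feats, function(f) {
    if (!identical(f$geometry$type, "Point"))
      stop("GeoJSON feature is not a Point")
    as.numeric(unlist(f$geometry$coordinates))
  }, numeric(2))
  if (length(feats) == 0L) return(PointSet(frame))
  PointSet(frame, x = pts[1L, ], y = pts[2L, ])
}

#' Write slide measures to CSV with a JSON provenance sidecar
#'
#' One row per slide; columns: slide_id, n_tdlus, adjusted_tissue_area_mm2,
#' tdlus_per_mm2, median_span_um, median_acini_per_tdlu, acini_per_mm2,
#' median_tdlu_area_mm2, plus any qualitative columns present. The sidecar
#' (\code{<path>.json}) records the configuration that produced the table.
#'
#' @param df data.frame of measures (slide_id plus measure columns)
#' @param path output CSV path
#' @param config named list of run configuration to record in the sidecar
#' @return \code{path}, invisibly
#' @export
writeMeasuresCSV <- function(df, path, config = list()) {
  stopifnot("slide_id" %in% names(df))
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- c(list(written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                    package = "tdlumetry",
                    version = as.character(utils::packageVersion("tdlumetry")),
                    n_slides = nrow(df)),
               config)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a measures CSV
#'
#' @param path CSV path written by \code{\link{writeMeasuresCSV}}
#' @return data.frame
#' @export
readMeasuresCSV <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read / write YAML run configuration
#'
#' @param path YAML file path
#' @return \code{readConfigYAML}: named list
#' @export
readConfigYAML <- function(path) yaml::read_yaml(path)

#' @rdname readConfigYAML
#' @param config named list
#' @export
writeConfigYAML <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
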