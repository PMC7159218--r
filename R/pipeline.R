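#' @include io.R backends.R agreement.R
NULL

#' Default run configuration
#'
#' All tunable parameters of the measuring pipeline with their defaults:
#' the published calibration coefficient 3.888, Russo thresholds 12 and 80,
#' strict-majority Baer rule, 15 um detection-match radius, and no minimum
#' TDLU area. Every output's JSON sidecar serializes the configuration in
#' force.
#'
#' @param resolutionUmPerPx pixel resolution of the input rasters
#' @param calibrationCoefficient acini-per-TDLU calibration factor
#' @param minTdluAreaMm2 exclude TDLU instances below this area
#' @param matchRadiusUm detection-matching radius for evaluation
#' @param useCalibratedTypes type Russo lobules on calibrated counts
#' @param seed RNG seed recorded with outputs
#' @return named list
#' @export
runConfig <- function(resolutionUmPerPx = 0.16,
                      calibrationCoefficient = 3.888,
                      minTdluAreaMm2 = 0,
                      matchRadiusUm = 15,
                      useCalibratedTypes = TRUE,
                      seed = 1L) {
  list(resolution_um_per_px = resolutionUmPerPx,
       calibration_coefficient = calibrationCoefficient,
       russo_thresholds = c(12, 80),
       baer_majority = 0.5,
       min_tdlu_area_mm2 = minTdluAreaMm2,
       match_radius_um = matchRadiusUm,
       use_calibrated_types = useCalibratedTypes,
       seed = as.integer(seed))
}

#' Measure and classify one slide
#'
#' Convenience wrapper running validate, assign, measure and classify on
#' one set of observations, returning a one-row data.frame ready for the
#' measures table.
#'
#' @param obs a \linkS4class{SlideObservations}
#' @param slideId identifier recorded in the row
#' @param model a \linkS4class{CalibrationModel}
#' @param minTdluAreaMm2 area filter forwarded to
#'   \code{\link{computeMeasures}}
#' @param useCalibratedTypes forwarded to \code{\link{classifySlide}}
#' @return list with \code{row} (one-row data.frame) and \code{records}
#'   (per-TDLU data.frame with slide_id)
#' @export
measureSlide <- function(obs, slideId = "slide1",
                         model = defaultCalibration(),
                         minTdluAreaMm2 = 0, useCalibratedTypes = TRUE) {
  res <- computeMeasures(obs, model, minTdluAreaMm2)
  qual <- classifySlide(res$records, useCalibrated = useCalibratedTypes)
  row <- cbind(data.frame(slide_id = slideId),
               as.data.frame(res$measures),
               data.frame(predominant_type = qual@predominantType,
                          baer_category = qual@baerCategory,
                          counts_type1 = qual@countsByType[[1L]],
                          counts_type2 = qual@countsByType[[2L]],
                          counts_type3 = qual@countsByType[[3L]]))
  records <- res$records
  if (nrow(records)) records <- cbind(slide_id = slideId, records)
  list(row = row, records = records, qualitative = qual)
}

#' Write a synthetic slide run directory
#'
#' Writes the rendered image (PNG), the ground-truth masks (TIFF), acini
#' points (CSV), true measures (CSV with JSON sidecar) and the generating
#' spec (YAML) into \code{outDir}.
#'
#' @param spec a \code{\link{slideSpec}}
#' @param outDir output directory (created if needed)
#' @param slideId slide identifier used in the files
#' @return the \linkS4class{SyntheticSlide}, invisibly
#' @export
cmdSimulate <- function(spec, outDir, slideId = "slide1") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  slide <- generateSlide(spec)
  png::writePNG(slide@image, file.path(outDir, "image.png"))
  writeMask(slide@truth@tissue, file.path(outDir, "tissue.tif"))
  writeMask(slide@truth@adipose, file.path(outDir, "adipose.tif"))
  writeMask(slide@truth@tdlus, file.path(outDir, "tdlus.tif"))
  writePointsCSV(slide@truth@acini, file.path(outDir, "acini.csv"),
                 slideId = slideId)
  tm <- cbind(data.frame(slide_id = slideId),
              as.data.frame(slide@trueMeasures))
  writeMeasuresCSV(tm, file.path(outDir, "true_measures.csv"),
                   config = unclass(spec))
  writeConfigYAML(unclass(spec), file.path(outDir, "spec.yaml"))
  invisible(slide)
}

#' Read the observations of a run directory
#'
#' Expects \code{tissue.tif}, \code{adipose.tif}, \code{tdlus.tif} and
#' \code{acini.csv} as written by \code{\link{cmdSimulate}} or an external
#' producer.
#'
#' @param dir run directory
#' @param resolutionUmPerPx raster resolution
#' @return a \linkS4class{SlideObservations}
#' @export
readObservationsDir <- function(dir, resolutionUmPerPx = 0.16) {
  need <- c("tissue.tif", "adipose.tif", "tdlus.tif", "acini.csv")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss))
    stop("missing input file(s) in ", dir, ": ", paste(miss, collapse = ", "))
  tissue <- readMask(file.path(dir, "tissue.tif"), resolutionUmPerPx,
                     as = "binary")
  adipose <- readMask(file.path(dir, "adipose.tif"), resolutionUmPerPx,
                      as = "binary")
  tdlus <- readMask(file.path(dir, "tdlus.tif"), resolutionUmPerPx,
                    as = "label")
  acini <- readPointsCSV(file.path(dir, "acini.csv"), slideFrame(tissue))
  if (is.list(acini)) stop("acini.csv must contain a single slide")
  SlideObservations(tissue = tissue, adipose = adipose, tdlus = tdlus,
                    acini = acini)
}

#' Run the measuring pipeline on a run directory
#'
#' Reads observations, validates them (a validation failure is an error),
#' computes the five quantitative measures and the qualitative
#' classification, and writes \code{measures.csv} (with JSON sidecar) and
#' \code{per_tdlu.csv} into \code{outDir}.
#'
#' @param inputDir run directory with masks and points
#' @param outDir output directory
#' @param config a \code{\link{runConfig}}
#' @param slideId slide identifier
#' @return the measures row data.frame, invisibly
#' @export
cmdMeasure <- function(inputDir, outDir = inputDir, config = runConfig(),
                       slideId = "slide1") {
  obs <- readObservationsDir(inputDir, config$resolution_um_per_px)
  viol <- validateObservations(obs)
  if (length(viol))
    stop("validation failed for ", inputDir, ": ",
         paste(viol, collapse = "; "))
  model <- defaultCalibration(config$calibration_coefficient)
  out <- measureSlide(obs, slideId, model, config$min_tdlu_area_mm2,
                      config$use_calibrated_types)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeMeasuresCSV(out$row, file.path(outDir, "measures.csv"),
                   config = config)
  utils::write.csv(out$records, file.path(outDir, "per_tdlu.csv"),
                   row.names = FALSE)
  message(sprintf("[measure] %s: %d TDLU(s), %.2f mm2 adjusted tissue",
                  slideId, out$row$n_tdlus,
                  out$row$adjusted_tissue_area_mm2))
  invisible(out$row)
}

#' Evaluate predicted observations against ground truth
#'
#' Per-slide detection F1 for acini (one-to-one matching within the
#' configured radius), Dice for the semantic TDLU mask and for the adipose
#' mask.
#'
#' @param pred,truth \linkS4class{SlideObservations} pairs
#' @param radiusUm detection-matching radius, micrometres
#' @return list with \code{f1}, \code{precision}, \code{recall},
#'   \code{diceTdlu}, \code{diceAdipose}
#' @export
evaluateObservations <- function(pred, truth, radiusUm = 15) {
  m <- matchDetections(pred@acini, truth@acini, radiusUm)
  frame <- truth@frame
  semantic <- function(o) BinaryMask(o@frame, o@tdlus@labels > 0L)
  dT <- dice(semantic(pred), semantic(truth))
  dA <- if (is(pred@adipose, "BinaryMask") && is(truth@adipose, "BinaryMask"))
    dice(pred@adipose, truth@adipose) else NA_real_
  list(f1 = m@f1, precision = m@precision, recall = m@recall,
       diceTdlu = dT, diceAdipose = dA)
}

#' Evaluate paired prediction/truth run directories
#'
#' Pairs slides by id, computes per-slide F1 and Dice scores, aggregates
#' them as mean and SD, and writes an evaluation JSON report.
#'
#' @param predDirs,truthDirs named character vectors of run directories;
#'   names are slide ids and must pair up exactly
#' @param outPath output JSON path (NULL to skip writing)
#' @param config a \code{\link{runConfig}}
#' @return the report as a list, invisibly
#' @export
cmdEvaluate <- function(predDirs, truthDirs, outPath = NULL,
                        config = runConfig()) {
  if (is.null(names(predDirs)) || is.null(names(truthDirs)))
    stop("predDirs and truthDirs must be named by slide id")
  unpaired <- c(setdiff(names(predDirs), names(truthDirs)),
                setdiff(names(truthDirs), names(predDirs)))
  if (length(unpaired))
    stop("unpaired slide id(s): ", paste(unique(unpaired), collapse = ", "))
  perSlide <- lapply(names(predDirs), function(id) {
    pred <- readObservationsDir(predDirs[[id]], config$resolution_um_per_px)
    truth <- readObservationsDir(truthDirs[[id]],
                                 config$resolution_um_per_px)
    c(list(slide_id = id),
      evaluateObservations(pred, truth, config$match_radius_um))
  })
  agg <- function(field) {
    v <- vapply(perSlide, function(s) s[[field]], numeric(1))
    aggregateScores(v[!is.na(v)])
  }
  report <- list(config = config,
                 per_slide = perSlide,
                 aggregate = list(f1 = agg("f1"),
                                  dice_tdlu = agg("diceTdlu"),
                                  dice_adipose = agg("diceAdipose")))
  if (!is.null(outPath))
    jsonlite::write_json(report, outPath, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  invisible(report)
}

#' ICC agreement table for paired measure tables
#'
#' Mirrors the layout of inter-method validation tables: one row per
#' quantitative measure, each an ICC(3,1) between the two raters/methods
#' over the slides both rated.
#'
#' @param a,b data.frames of measures (from \code{\link{readMeasuresCSV}})
#'   with a shared \code{slide_id} column
#' @param measures columns to compare
#' @return data.frame with measure, icc, ci_low, ci_high, n
#' @export
measureAgreementTable <- function(a, b,
                                  measures = c("tdlus_per_mm2",
                                               "median_span_um",
                                               "median_acini_per_tdlu")) {
  ids <- intersect(a$slide_id, b$slide_id)
  if (length(ids) < 2L) stop("need >= 2 paired slides")
  a <- a[match(ids, a$slide_id), ]
  b <- b[match(ids, b$slide_id), ]
  rows <- lapply(measures, function(m) {
    keep <- !(is.na(a[[m]]) | is.na(b[[m]]))
    r <- icc31(cbind(a[[m]][keep], b[[m]][keep]))
    data.frame(measure = m, icc = r@statistic, ci_low = r@ciLow,
               ci_high = r@ciHigh, n = r@nSubjects)
  })
  do.call(rbind, rows)
}

#' Fit a calibration model from a paired-counts table
#'
#' Reads a CSV with columns \code{auto} and \code{manual} (median acini per
#' TDLU from the automated pipeline and from observers), fits the
#' through-origin calibration and writes the model, with free-intercept
#' diagnostics, as JSON. Refuses fewer than 3 pairs.
#'
#' @param pairsPath CSV path with columns auto, manual
#' @param outPath output JSON path (NULL to skip writing)
#' @return the fitted \linkS4class{CalibrationModel}, invisibly
#' @export
cmdCalibrate <- function(pairsPath, outPath = NULL) {
  df <- utils::read.csv(pairsPath)
  miss <- setdiff(c("auto", "manual"), names(df))
  if (length(miss))
    stop("pairs CSV missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) < 3L)
    stop("calibration needs at least 3 pairs, got ", nrow(df))
  model <- fitCalibration(df$auto, df$manual)
  if (!is.null(outPath))
    jsonlite::write_json(
      list(coefficient = model@coefficient, intercept = 0,
           n_pairs = model@nPairs, source = model@source,
           intercept_estimate = model@interceptEstimate,
           intercept_se = model@interceptSE),
      outPath, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(model)
}
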