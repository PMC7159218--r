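#' @include measures.R
NULL

#' Russo lobule type from an acini count
#'
#' Type 1 (least developed): fewer than 12 acini per lobule; type 2: 12 to
#' 80; type 3 (fully developed): more than 80. Counts are expected on the
#' calibrated (manual-equivalent) scale, where the thresholds were defined.
#' The boundary value 80 is assigned to type 2.
#'
#' @param aciniCount acini count(s), >= 0; vectorized
#' @return integer type(s) in \{1, 2, 3\}
#' @export
russoType <- function(aciniCount) {
  if (any(is.na(aciniCount)) || any(aciniCount < 0))
    stop("aciniCount must be non-negative")
  ifelse(aciniCount < 12, 1L, ifelse(aciniCount <= 80, 2L, 3L))
}

#' Predominant lobule type of a slide
#'
#' The modal Russo type over the slide's TDLUs; ties are broken toward the
#' higher (less involuted) type, a deterministic and conservative choice
#' that flags less involution.
#'
#' @param types integer vector of per-TDLU types in \{1, 2, 3\}
#' @return the predominant type, or NA for an empty slide
#' @export
predominantType <- function(types) {
  if (!length(types)) return(NA_integer_)
  counts <- tabulate(types, nbins = 3L)
  max(which(counts == max(counts)))
}

#' Baer slide category from per-TDLU types
#'
#' Categories: "no_type1" (zero type-1 lobules);
#' "predominantly_type1_no_type3" (more than half type 1 and zero type 3);
#' "mixed" (all others). "Predominantly" is read as a strict majority.
#'
#' @param types integer vector of per-TDLU types in \{1, 2, 3\}
#' @return category string, or NA for an empty slide
#' @export
baerCategory <- function(types) {
  if (!length(types)) return(NA_character_)
  counts <- tabulate(types, nbins = 3L)
  if (counts[1L] == 0L) return("no_type1")
  if (counts[1L] > length(types) / 2 && counts[3L] == 0L)
    return("predominantly_type1_no_type3")
  "mixed"
}

#' Majority-vote consensus across raters
#'
#' Returns the label held by a strict majority of raters, or NA when no
#' strict majority exists (flagging the case for adjudication).
#'
#' @param labels vector of categorical labels, one per rater (>= 2 raters)
#' @return the consensus label, or NA
#' @export
consensusVote <- function(labels) {
  if (length(labels) < 2L) stop("consensus requires at least 2 raters")
  tab <- table(labels)
  top <- tab[tab == max(tab)]
  if (length(top) != 1L || top[[1L]] <= length(labels) / 2)
    return(labels[NA_integer_][1L])   # NA of the input's type
  names(top)
}

#' Classify a slide's TDLUs qualitatively
#'
#' Applies Russo typing to per-TDLU acini counts and derives the slide's
#' predominant type and Baer category. By default counts are taken on the
#' calibrated scale (\code{acini_count_calibrated} of the per-TDLU records);
#' set \code{useCalibrated = FALSE} to type raw automated counts instead.
#'
#' @param records per-TDLU data.frame from \code{\link{computeMeasures}}
#' @param useCalibrated use calibrated counts (default) or raw counts
#' @return a \linkS4class{QualitativeResult}
#' @export
classifySlide <- function(records, useCalibrated = TRUE) {
  counts <- if (useCalibrated) records$acini_count_calibrated
            else records$acini_count_raw
  types <- if (length(counts)) as.integer(russoType(counts)) else integer()
  new("QualitativeResult",
      perTdluTypes = types,
      predominantType = as.integer(predominantType(types)),
      baerCategory = baerCategory(types),
      countsByType = structure(tabulate(types, nbins = 3L),
                               names = c("type1", "type2", "type3")))
}

setMethod("show", "QualitativeResult", function(object) {
  cat("QualitativeResult\n")
  cat(sprintf("  TDLUs: %d (type1 %d, type2 %d, type3 %d)\n",
              length(object@perTdluTypes), object@countsByType[1L],
              object@countsByType[2L], object@countsByType[3L]))
  cat(sprintf("  predominant type: %s\n",
              ifelse(is.na(object@predominantType), "undefined",
                     object@predominantType)))
  cat(sprintf("  Baer category: %s\n",
              ifelse(is.na(object@baerCategory), "undefined",
                     object@baerCategory)))
})
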