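#' @include slideModel.R
NULL

#' Match point detections against ground truth
#'
#' One-to-one, maximum-cardinality matching between predicted and
#' ground-truth points among all pairs closer than \code{radiusUm}
#' (maximum bipartite matching on the thresholded distance graph). The
#' result is deterministic and invariant, in cardinality, to permutation of
#' the inputs. Precision = tp / (tp + fp), recall = tp / (tp + fn) (each 0
#' when its denominator is 0) and F1 is their harmonic mean (0 when both
#' are 0).
#'
#' The matching radius is a free parameter of the evaluation; the package
#' default of 15 um is on the order of an acinus radius and is recorded in
#' all evaluation output.
#'
#' @param pred predicted \linkS4class{PointSet}
#' @param gt ground-truth \linkS4class{PointSet} (same frame)
#' @param radiusUm maximum centre-to-centre distance (micrometres) for a hit
#' @return a \linkS4class{MatchResult}
#' @export
matchDetections <- function(pred, gt, radiusUm = 15) {
  stopifnot(radiusUm > 0)
  if (!sameFrame(pred@frame, gt@frame))
    stop("pred and gt must share a frame")
  res <- pred@frame@resolutionUmPerPx
  np <- nrow(pred@coords); ng <- nrow(gt@coords)
  pairs <- matrix(integer(), 0L, 2L, dimnames = list(NULL, c("pred", "gt")))
  tp <- 0L
  if (np > 0L && ng > 0L) {
    radiusPx <- radiusUm / res
    d2 <- outer(pred@coords[, 1L], gt@coords[, 1L], "-")^2 +
          outer(pred@coords[, 2L], gt@coords[, 2L], "-")^2
    hits <- which(d2 <= radiusPx^2, arr.ind = TRUE)
    if (nrow(hits)) {
      g <- igraph::make_bipartite_graph(
        types = c(rep(FALSE, np), rep(TRUE, ng)),
        edges = as.vector(t(cbind(hits[, 1L], np + hits[, 2L]))))
      m <- igraph::max_bipartite_match(g)$matching
      matched <- which(!is.na(m[seq_len(np)]))
      if (length(matched)) {
        pairs <- cbind(pred = as.integer(matched),
                       gt = as.integer(m[matched]) - np)
        tp <- nrow(pairs)
      }
    }
  }
  fp <- np - tp; fn <- ng - tp
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  new("MatchResult", tp = tp, fp = as.integer(fp), fn = as.integer(fn),
      pairs = pairs, precision = precision, recall = recall, f1 = f1)
}

setMethod("show", "MatchResult", function(object) {
  cat(sprintf(
    "MatchResult: tp %d, fp %d, fn %d | precision %.3f, recall %.3f, F1 %.3f\n",
    object@tp, object@fp, object@fn, object@precision, object@recall,
    object@f1))
})

#' Dice similarity coefficient between two binary masks
#'
#' 2|A and B| / (|A| + |B|). Two empty masks score 1 (perfect agreement on
#' absence). Dice is exactly the F1 score computed on pixel sets, so
#' segmentation and detection evaluation share one definition.
#'
#' @param a,b \linkS4class{BinaryMask}s on the same frame
#' @return Dice coefficient in [0, 1]
#' @export
dice <- function(a, b) {
  if (!sameFrame(a@frame, b@frame)) stop("masks must share a frame")
  na <- sum(a@pixels); nb <- sum(b@pixels)
  if (na + nb == 0L) return(1)
  2 * sum(a@pixels & b@pixels) / (na + nb)
}

#' Intraclass correlation ICC(3,1)
#'
#' Two-way mixed effects, consistency, single rater: from the two-way
#' (subjects x raters) ANOVA decomposition,
#' ICC = (MS_R - MS_E) / (MS_R + (k - 1) MS_E), where MS_R is the
#' between-subject mean square and MS_E the residual mean square. The
#' confidence interval uses the F-distribution bounds
#' F_L = F / qf(1 - alpha/2; n-1, (n-1)(k-1)) and
#' F_U = F * qf(1 - alpha/2; (n-1)(k-1), n-1) with F = MS_R / MS_E,
#' mapped through (F - 1) / (F + k - 1).
#'
#' Consistency ICC is invariant to per-rater additive shifts and to a
#' common positive affine rescaling of all cells.
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns; no
#'   missing cells, n >= 2 subjects and k >= 2 raters
#' @param conf confidence level (default 0.95)
#' @return an \linkS4class{AgreementResult} with method "icc_3_1"
#' @export
icc31 <- function(ratings, conf = 0.95) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ratings must have no missing cells")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters")
  gm <- mean(ratings)
  rowm <- rowMeans(ratings); colm <- colMeans(ratings)
  SSR <- k * sum((rowm - gm)^2)
  SSC <- n * sum((colm - gm)^2)
  SST <- sum((ratings - gm)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (MSR <= 0 && MSE <= 1e-300)
    stop("zero total variance: ICC undefined")
  if (MSE <= 1e-300) {            # perfect consistency
    icc <- 1; lo <- 1; hi <- 1
  } else {
    icc <- (MSR - MSE) / (MSR + (k - 1) * MSE)
    F0 <- MSR / MSE
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    alpha <- 1 - conf
    FL <- F0 / stats::qf(1 - alpha / 2, df1, df2)
    FU <- F0 * stats::qf(1 - alpha / 2, df2, df1)
    lo <- (FL - 1) / (FL + k - 1)
    hi <- (FU - 1) / (FU + k - 1)
  }
  new("AgreementResult", statistic = icc, ciLow = lo, ciHigh = hi,
      pValue = NA_real_, method = "icc_3_1", nSubjects = as.integer(n),
      nRaters = as.integer(k))
}

#' Fleiss' kappa for categorical ratings
#'
#' Chance-corrected agreement for a fixed number of raters classifying
#' subjects into categories: kappa = (Pbar - Pbar_e) / (1 - Pbar_e), with
#' Pbar the mean over subjects of the observed pairwise agreement and
#' Pbar_e = sum_j p_j^2 from the marginal category proportions. The
#' significance test is the large-sample z = kappa / SE_0(kappa) against
#' kappa = 0.
#'
#' @param counts integer matrix, subjects in rows, categories in columns;
#'   each cell the number of raters assigning that category
#' @param ratersPerSubject raters per subject; every row must sum to it
#' @return an \linkS4class{AgreementResult} with method "fleiss_kappa"
#' @export
fleissKappa <- function(counts, ratersPerSubject) {
  counts <- as.matrix(counts)
  N <- nrow(counts); n <- ratersPerSubject
  if (n < 2L) stop("need at least 2 raters per subject")
  if (any(rowSums(counts) != n))
    stop("every row of counts must sum to ratersPerSubject")
  pj <- colSums(counts) / (N * n)
  Pe <- sum(pj^2)
  if (Pe >= 1 - 1e-12)
    stop("all ratings in one category: kappa undefined")
  Pi <- (rowSums(counts^2) - n) / (n * (n - 1))
  Pbar <- mean(Pi)
  kappa <- (Pbar - Pe) / (1 - Pe)
  qj <- 1 - pj
  SE0 <- sqrt(2 / (N * n * (n - 1))) *
    sqrt(sum(pj * qj)^2 - sum(pj * qj * (qj - pj))) / sum(pj * qj)
  z <- kappa / SE0
  p <- 2 * stats::pnorm(-abs(z))
  new("AgreementResult", statistic = kappa, ciLow = NA_real_,
      ciHigh = NA_real_, pValue = p, method = "fleiss_kappa",
      nSubjects = as.integer(N), nRaters = as.integer(n))
}

setMethod("show", "AgreementResult", function(object) {
  if (object@method == "icc_3_1")
    cat(sprintf("ICC(3,1) = %.3f, 95%% CI (%.3f, %.3f), n = %d, k = %d\n",
                object@statistic, object@ciLow, object@ciHigh,
                object@nSubjects, object@nRaters))
  else
    cat(sprintf("Fleiss' kappa = %.3f (p = %.3g), n = %d, raters = %d\n",
                object@statistic, object@pValue, object@nSubjects,
                object@nRaters))
})

#' Association tests used in involution studies
#'
#' Thin wrappers over the standard nonparametric tests relating involution
#' measures to covariates such as age or menopausal status. Ties are
#' handled by midranks throughout (the underlying base-R implementations).
#'
#' \describe{
#'   \item{spearman}{rank correlation of paired numeric vectors x, y}
#'   \item{mann_whitney_u}{two-sample rank-sum; x numeric, y a two-level group}
#'   \item{kruskal_wallis}{k-sample rank test; x numeric, y a grouping factor}
#'   \item{chi_squared}{independence of two categorical vectors (or x a table)}
#' }
#'
#' @param test one of "spearman", "mann_whitney_u", "kruskal_wallis",
#'   "chi_squared"
#' @param x,y data as described per test
#' @return list with \code{statistic}, \code{p.value}, \code{method}
#' @export
associationTest <- function(test = c("spearman", "mann_whitney_u",
                                     "kruskal_wallis", "chi_squared"),
                            x, y = NULL) {
  test <- match.arg(test)
  ht <- switch(test,
    spearman = suppressWarnings(
      stats::cor.test(x, y, method = "spearman")),
    mann_whitney_u = {
      g <- factor(y)
      if (nlevels(g) != 2L) stop("mann_whitney_u needs exactly 2 groups")
      suppressWarnings(stats::wilcox.test(x[g == levels(g)[1L]],
                                          x[g == levels(g)[2L]]))
    },
    kruskal_wallis = {
      g <- factor(y)
      if (any(table(g) < 1L) || nlevels(g) < 2L)
        stop("kruskal_wallis needs >= 2 nonempty groups")
      stats::kruskal.test(x, g)
    },
    chi_squared = {
      tab <- if (is.table(x) || is.matrix(x)) as.table(x) else table(x, y)
      suppressWarnings(stats::chisq.test(tab))
    })
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       method = test)
}

#' Mean and standard deviation of per-slide scores
#'
#' Aggregates per-slide F1 or Dice values in the conventional
#' "mean +/- SD" reporting style.
#'
#' @param values numeric vector of per-slide scores
#' @return list with \code{mean}, \code{sd} (NA for a single slide), \code{n}
#' @export
aggregateScores <- function(values) {
  list(mean = mean(values), sd = stats::sd(values), n = length(values))
}
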