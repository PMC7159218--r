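# Fixture builders and independent oracles used across the suite.
# Everything here is computed from first principles, independent of the
# package's own code paths.

# Pixel-centre coordinates (x, y) of a rasterized ellipse with semi-axes
# a, b (pixels) rotated by theta, centred at (cx, cy).
ellipseCoords <- function(a, b, theta = 0, cx = 0, cy = 0) {
  r <- ceiling(max(a, b)) + 2
  xs <- seq(floor(cx - r), ceiling(cx + r))
  ys <- seq(floor(cy - r), ceiling(cy + r))
  g <- expand.grid(x = xs, y = ys)
  dx <- g$x - cx; dy <- g$y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  as.matrix(g[inside, c("x", "y")])
}

discCoords <- function(r, cx = 0, cy = 0) ellipseCoords(r, r, 0, cx, cy)

# Embed instance pixel coordinate sets into a LabelMask; coords are shifted
# to positive territory automatically.
coordsToLabelMask <- function(coordList, res = 1, pad = 2) {
  allxy <- do.call(rbind, coordList)
  ox <- min(allxy[, 1]) - pad; oy <- min(allxy[, 2]) - pad
  w <- max(allxy[, 1]) - ox + pad + 1; h <- max(allxy[, 2]) - oy + pad + 1
  frame <- SlideFrame(w, h, res)
  lab <- matrix(0L, h, w)
  for (i in seq_along(coordList)) {
    xy <- coordList[[i]]
    lab[cbind(xy[, 2] - oy + 1, xy[, 1] - ox + 1)] <- i
  }
  LabelMask(frame, lab)
}

# A small fully-consistent observation set: two square TDLUs in a
# rectangular tissue, a given adipose fraction as a mask, and acini planted
# at known positions.
makeToyObservations <- function(res = 1) {
  frame <- SlideFrame(100, 80, res)
  tissue <- matrix(FALSE, 80, 100); tissue[6:75, 6:95] <- TRUE
  adipose <- matrix(FALSE, 80, 100); adipose[60:75, 70:95] <- TRUE
  lab <- matrix(0L, 80, 100)
  lab[11:30, 11:30] <- 1L    # 20x20 square, centre (20, 20)
  lab[11:40, 51:80] <- 2L    # 30x30 square, centre (65, 25)
  acini <- rbind(c(15, 15), c(25, 25), c(20, 20),        # 3 in TDLU 1
                 c(60, 20), c(70, 30),                   # 2 in TDLU 2
                 c(40, 60))                              # background
  SlideObservations(tissue = BinaryMask(frame, tissue),
                    adipose = BinaryMask(frame, adipose),
                    tdlus = LabelMask(frame, lab),
                    acini = PointSet(frame, x = acini[, 1], y = acini[, 2]))
}

# Independent ICC(3,1) oracle: mean squares from base R's two-way ANOVA
# fit, not from the package's decomposition.
iccOracleAov <- function(ratings) {
  n <- nrow(ratings); k <- ncol(ratings)
  d <- data.frame(y = as.vector(ratings),
                  subj = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse)
}

# Independent Fleiss' kappa oracle: direct transcription of the published
# formulation from the category-count table.
fleissOracle <- function(counts, n) {
  N <- nrow(counts)
  pj <- colSums(counts) / (N * n)
  Pi <- (rowSums(counts^2) - n) / (n * (n - 1))
  (mean(Pi) - sum(pj^2)) / (1 - sum(pj^2))
}

# A quick small synthetic spec used where full-size defaults would be slow.
smallSpec <- function(seed, nTdlus = 5, widthPx = 768, heightPx = 768,
                      adipose = 0.25,
                      aciniPerTdlu = list(dist = "lognormal",
                                          meanlog = log(12), sdlog = 0.6,
                                          min = 1, max = 60)) {
  slideSpec(widthPx = widthPx, heightPx = heightPx, resolutionUmPerPx = 2,
            nTdlus = nTdlus,
            aciniPerTdlu = aciniPerTdlu,
            tdluRadiusUm = list(dist = "uniform", min = 80, max = 180),
            acinusRadiusUm = list(dist = "uniform", min = 10, max = 16),
            adiposeFractionTarget = adipose, seed = seed)
}
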