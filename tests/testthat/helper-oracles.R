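## Independent oracles used to freeze expected values. These deliberately
## re-derive results by brute force / closed form, sharing no code with the
## implementation paths they check.

## Literal point-to-line construction of the triangle threshold: loop over
## candidate bins, measure the perpendicular distance geometrically.
oracleTriangleBin <- function(values, nBins = 64) {
  values <- values[is.finite(values)]
  breaks <- seq(min(values), max(values), length.out = nBins + 1)
  counts <- integer(nBins)
  for (i in seq_len(nBins)) {
    if (i == nBins)
      counts[i] <- sum(values >= breaks[i] & values <= breaks[i + 1])
    else counts[i] <- sum(values >= breaks[i] & values < breaks[i + 1])
  }
  peak <- which.max(counts)
  nonEmpty <- which(counts > 0)
  tail <- nonEmpty[which.max(abs(nonEmpty - peak))]
  p1 <- c(0, 1)
  p2 <- c(1, counts[tail] / counts[peak])
  span <- seq(peak, tail, by = if (tail > peak) 1 else -1)
  bestBin <- NA_integer_; bestD <- -Inf
  for (b in span) {
    q <- c((b - peak) / (tail - peak), counts[b] / counts[peak])
    ## area of the parallelogram over the base length
    d <- abs((p2[1] - p1[1]) * (p1[2] - q[2]) -
             (p1[1] - q[1]) * (p2[2] - p1[2])) /
      sqrt(sum((p2 - p1)^2))
    if (d > bestD + 1e-12) { bestD <- d; bestBin <- b }
  }
  bestBin
}

oracleTriangleThreshold <- function(values, nBins = 64) {
  b <- oracleTriangleBin(values, nBins)
  breaks <- seq(min(values), max(values), length.out = nBins + 1)
  (breaks[b] + breaks[b + 1]) / 2
}

## Exhaustive integer-lag scan of the normalized cross-correlation between
## two images over their overlap: ref(p) vs mov(p + lag).
oracleBestLag <- function(ref, mov, maxShift) {
  h <- nrow(ref); w <- ncol(ref)
  best <- c(NA, NA); bestC <- -Inf
  for (dy in -maxShift:maxShift) for (dx in -maxShift:maxShift) {
    rr <- max(1, 1 - dy):min(h, h - dy)
    cc <- max(1, 1 - dx):min(w, w - dx)
    a <- ref[rr, cc]
    b <- mov[rr + dy, cc + dx]
    if (length(a) < 64) next
    cv <- suppressWarnings(stats::cor(as.vector(a), as.vector(b)))
    if (is.finite(cv) && cv > bestC) { bestC <- cv; best <- c(dx, dy) }
  }
  list(dx = best[1], dy = best[2], cor = bestC)
}

## Dense-grid trapezoid quadrature of a sum of Gaussian bands over a window.
oracleBandIntegral <- function(bands, lo, hi, step = 0.01) {
  x <- seq(lo, hi, by = step)
  y <- rep(0, length(x))
  for (i in seq_len(nrow(bands)))
    y <- y + bands[i, 3] * exp(-0.5 * ((x - bands[i, 1]) / bands[i, 2])^2)
  sum((utils::head(y, -1) + utils::tail(y, -1)) / 2 * diff(x))
}

## Small, fast phantom configurations shared across tests.
testPhantomSpec <- function(..., size = 96L) {
  fov <- size * 39.0625e-3           # keep the 39 nm pixel of a 20 um map
  defaults <- list(imageSizePx = c(size, size),
                   fieldOfViewUm = c(fov, fov),
                   nCells = 2L, ibCountRange = c(1L, 2L),
                   ibRadiusRangePx = c(3, 5),
                   cellMajorUm = c(1.0, 1.8), cellMinorUm = c(0.5, 0.8))
  do.call(phantomSpec, utils::modifyList(defaults, list(...)))
}

## a noise-free, drift-free variant
cleanPhantomSpec <- function(...) {
  defaults <- list(edgeBlurSigmaPx = 0, amplitudeNoiseSd = 0,
                   interMapDrift = c(0, 0, 0), pllLineDrift = c(0, 0))
  do.call(testPhantomSpec, utils::modifyList(defaults, list(...)))
}

truthSegmentation <- function(truth) {
  SegmentationMaps(cellLabels(truth), ibLabels(truth),
                   ibTable(truth)[, c("ib_id", "cell_id")])
}

## mark a pair as already aligned (identity transform) without resampling
identityRegistered <- function(pair) {
  pair@transform <- diag(3)
  pair
}

meanResidualPx <- function(A, B, supportMask) {
  idx <- which(supportMask, arr.ind = TRUE)
  xy <- cbind(idx[, 2] - 1, idx[, 1] - 1)
  d <- applyAffine(A, xy) - applyAffine(B, xy)
  mean(sqrt(rowSums(d^2)))
}
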