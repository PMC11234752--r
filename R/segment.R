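## Pixel classification: background / cell / inclusion body.

#' Triangle-algorithm histogram threshold
#'
#' Classic geometric threshold construction: build a histogram of the
#' values, draw a line from the histogram peak to the farthest non-empty
#' tail bin, and return the centre of the bin (between peak and tail)
#' maximising the perpendicular distance between the histogram and that
#' line. Axes are normalised to the peak-tail span (bin index) and the peak
#' count before measuring distance, so the construction is invariant to
#' affine rescaling of the input values. Ties are resolved toward the bin
#' closest to the peak; if the peak is central, the farther of the two tails
#' is used (ties toward the lower bin).
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @param nBins Number of histogram bins.
#' @return Threshold in intensity units (a bin centre).
#' @examples
#' x <- c(rnorm(900, 1, 0.05), rnorm(100, 2, 0.05))
#' triangleThreshold(x)
#' @export
triangleThreshold <- function(values, nBins = 64) {
  values <- values[is.finite(values)]
  if (length(values) < 2L || diff(range(values)) == 0)
    stop("triangle threshold undefined for constant input")
  breaks <- seq(min(values), max(values), length.out = nBins + 1)
  ## exact binning: [b_i, b_{i+1}) with the last bin closed on the right
  counts <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE),
                     nBins)
  peak <- which.max(counts)
  nonEmpty <- which(counts > 0)
  tail <- nonEmpty[which.max(abs(nonEmpty - peak))]
  if (tail == peak)
    stop("triangle threshold undefined: single occupied bin")
  span <- seq(peak, tail, by = if (tail > peak) 1L else -1L)
  ## normalised coordinates: x in [0, 1] along the span, y by peak count
  xs <- (span - peak) / (tail - peak)
  ys <- counts[span] / counts[peak]
  ## perpendicular distance to the line from (0, 1) to (1, ys[tail])
  yt <- ys[length(ys)]
  d <- abs((yt - 1) * xs - ys + 1) / sqrt((yt - 1)^2 + 1)
  ## ties (within numerical noise) resolve toward the bin nearest the peak
  bin <- span[which(d > max(d) - 1e-12)[1]]
  (breaks[bin] + breaks[bin + 1]) / 2
}

#' Segment cells in an AFM-IR dataset
#'
#' Produces an instance label map of cells from the IR amplitude (trace)
#' map. The backend contract is any function mapping a 2D intensity matrix
#' to an integer instance label map of the same shape (e.g. an external
#' deep-learning model adapter); the built-in \code{"fallback"} backend is
#' Gaussian smoothing, a global triangle threshold, hole filling, a small
#' opening, and a distance-transform watershed split. Each instance is then
#' eroded by a disk (discarding membrane pixels), instances touching the
#' image border are discarded, and labels are renumbered contiguously.
#'
#' @param dataset An [AFMIRDataset-class] with an IRAmplitude trace map, or
#'   a plain intensity matrix.
#' @param backend \code{"fallback"} or a function \code{(matrix) ->} label
#'   matrix.
#' @param erosionRadiusPx Membrane erosion disk radius (px).
#' @param smoothSigmaPx Gaussian smoothing sigma of the fallback backend.
#' @param nBins Histogram bins of the fallback threshold.
#' @return Integer cell label matrix (0 = background).
#' @export
segmentCells <- function(dataset, backend = "fallback", erosionRadiusPx = 2,
                         smoothSigmaPx = 1, nBins = 64) {
  if (is(dataset, "AFMIRDataset")) {
    cm <- getChannel(dataset, "IRAmplitude", "trace")
    img <- mapData(cm); valid <- validMask(cm)
  } else {
    img <- as.matrix(dataset); valid <- is.finite(img)
  }
  if (is.function(backend)) {
    lab <- .asLabelMatrix(backend(img))
    if (!identical(dim(lab), dim(img)))
      stop("segmentation backend returned a mismatched shape")
  } else if (identical(backend, "fallback")) {
    lab <- .fallbackCellBackend(img, valid, smoothSigmaPx, nBins)
  } else stop("unknown backend")
  .postprocessCells(lab, erosionRadiusPx)
}

.fallbackCellBackend <- function(img, valid, smoothSigmaPx, nBins) {
  ## invalid pixels are filled with the valid median before smoothing so
  ## they cannot drag the histogram or bleed into neighbouring pixels
  if (!any(valid)) return(matrix(0L, nrow(img), ncol(img)))
  img[!valid] <- stats::median(img[valid])
  sm <- if (smoothSigmaPx > 0) .em(EBImage::gblur(img, sigma = smoothSigmaPx))
        else img
  thr <- tryCatch(triangleThreshold(sm[valid], nBins),
                  error = function(e) NA_real_)
  if (is.na(thr)) return(matrix(0L, nrow(img), ncol(img)))
  fg <- sm > thr & valid
  fg <- .em(EBImage::fillHull(fg)) > 0
  k <- diskKernel(2)
  fg <- .em(EBImage::dilate(EBImage::erode(fg, k), k)) > 0
  if (!any(fg)) return(matrix(0L, nrow(img), ncol(img)))
  dm <- .em(EBImage::distmap(fg))
  .asLabelMatrix(.em(EBImage::watershed(dm, tolerance = 1)))
}

.postprocessCells <- function(lab, erosionRadiusPx) {
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (!length(ids)) {
    warning("no cells found")
    return(lab)
  }
  h <- nrow(lab); w <- ncol(lab)
  out <- matrix(0L, h, w)
  k <- if (erosionRadiusPx > 0) diskKernel(erosionRadiusPx) else NULL
  nextId <- 0L
  for (id in ids) {
    m <- lab == id
    touches <- any(m[1, ]) || any(m[h, ]) || any(m[, 1]) || any(m[, w])
    if (touches) next                       # border-intersecting cell
    if (!is.null(k)) m <- .em(EBImage::erode(m, k)) > 0
    if (!any(m)) next
    nextId <- nextId + 1L
    out[m] <- nextId
  }
  if (nextId == 0L) warning("no interior cells after border discard")
  out
}

#' Segment inclusion bodies within cells
#'
#' Per cell: the intensity distribution of its interior pixels in the
#' (registered) 1625 cm^-1 IR amplitude map is thresholded with the triangle
#' algorithm, the supra-threshold mask is cleaned by a binary opening with a
#' disk structuring element, pixels outside the (eroded) cell mask are
#' discarded, and connected components become IB instances. A consequence of
#' the opening is a minimum detectable IB radius equal to the structuring
#' element radius. Cells with too few interior pixels for a meaningful
#' histogram are skipped with a warning.
#'
#' @param amp1625 Registered 1625 cm^-1 amplitude [ChannelMap-class] or
#'   matrix.
#' @param cellLabels Integer cell label map from [segmentCells()].
#' @param openingRadiusPx Disk radius of the binary opening (px).
#' @param nBins Histogram bins for the per-cell threshold.
#' @param minCellPx Minimum interior pixels per cell.
#' @param pooled Pool pixels of all cells into one histogram instead of
#'   thresholding per cell (sensitivity-analysis mode).
#' @return A [SegmentationMaps-class].
#' @export
segmentIbs <- function(amp1625, cellLabels, openingRadiusPx = 2, nBins = 64,
                       minCellPx = 16, pooled = FALSE) {
  amp <- if (is(amp1625, "ChannelMap")) amp1625@data else as.matrix(amp1625)
  av <- if (is(amp1625, "ChannelMap")) amp1625@valid else is.finite(amp)
  cellLabels <- .asLabelMatrix(cellLabels)
  stopifnot(identical(dim(amp), dim(cellLabels)))
  ids <- setdiff(sort(unique(as.vector(cellLabels))), 0L)
  h <- nrow(amp); w <- ncol(amp)
  ibLab <- matrix(0L, h, w)
  own <- list()
  k <- diskKernel(openingRadiusPx)
  pooledThr <- if (pooled && length(ids))
    tryCatch(triangleThreshold(amp[cellLabels > 0 & av], nBins),
             error = function(e) NA_real_) else NA_real_
  nextIb <- 0L
  for (id in ids) {
    inCell <- cellLabels == id & av
    if (sum(inCell) < minCellPx) {
      warning("cell ", id, " skipped: fewer than ", minCellPx,
              " interior pixels")
      next
    }
    thr <- if (pooled) pooledThr else
      tryCatch(triangleThreshold(amp[inCell], nBins),
               error = function(e) NA_real_)
    if (is.na(thr)) next
    m <- inCell & amp > thr
    if (!any(m)) next
    m <- .em(EBImage::dilate(EBImage::erode(m, k), k)) > 0   # binary opening
    m <- m & cellLabels == id        # opening never leaves the cell support
    if (!any(m)) next
    comp <- .asLabelMatrix(.em(EBImage::bwlabel(m)))
    for (c0 in seq_len(max(comp))) {
      nextIb <- nextIb + 1L
      ibLab[comp == c0] <- nextIb
      own[[nextIb]] <- data.frame(ib_id = nextIb, cell_id = id)
    }
  }
  ibToCell <- if (length(own)) do.call(rbind, own)
  else data.frame(ib_id = integer(), cell_id = integer())
  SegmentationMaps(cellLabels, ibLab, ibToCell)
}
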