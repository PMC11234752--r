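## Per-cell and per-IB quantification.

#' Second-moment geometry of a binary mask
#'
#' Centroid, orientation and major-axis extent from the inertia tensor of
#' the mask pixels. Coordinates are 0-based (x = column, y = row, y axis
#' pointing down). \code{majorLength} is the full extent of the mask
#' projected on the major axis (in pixels, counting pixel width). Masks with
#' an isotropic inertia tensor (e.g. disks) have no defined orientation and
#' are flagged degenerate.
#'
#' @param mask Logical matrix.
#' @return List: centroid (x, y), orientation (rad, in (-pi/2, pi/2]),
#'   majorLength (px), area (px), degenerate (flag).
#' @export
cellGeometry <- function(mask) {
  mask <- as.matrix(mask) > 0
  if (!any(mask)) stop("empty mask")
  idx <- which(mask, arr.ind = TRUE)
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  cx <- mean(x); cy <- mean(y)
  mu20 <- mean((x - cx)^2); mu02 <- mean((y - cy)^2)
  mu11 <- mean((x - cx) * (y - cy))
  aniso <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  degenerate <- aniso <= 1e-9 * (mu20 + mu02 + 1e-12)
  theta <- if (degenerate) 0 else 0.5 * atan2(2 * mu11, mu20 - mu02)
  u <- c(cos(theta), sin(theta))
  proj <- (x - cx) * u[1] + (y - cy) * u[2]
  list(centroid = c(x = cx, y = cy), orientation = theta,
       majorLength = diff(range(proj)) + 1, area = nrow(idx),
       degenerate = degenerate)
}

#' Normalised polar position of an IB within its host cell
#'
#' Signed projection of the IB centroid onto the cell's major axis unit
#' vector, divided by the half extent of the cell along that axis, clipped
#' to [-1, 1]. The axis vector is oriented so its image-x component is
#' positive: the positive pole is the one on the right-hand side of the map
#' (the sign itself carries no biology -- pole age is not observable here).
#' Degenerate (orientation-free) cells give position 0 with a flag.
#'
#' @param ibCentroid Numeric (x, y) of the IB centroid (0-based px).
#' @param geometry Output of [cellGeometry()] for the host cell.
#' @return List: position in [-1, 1], degenerate flag.
#' @export
polarPosition <- function(ibCentroid, geometry) {
  if (isTRUE(geometry$degenerate))
    return(list(position = 0, degenerate = TRUE))
  u <- c(cos(geometry$orientation), sin(geometry$orientation))
  if (u[1] < 0 || (u[1] == 0 && u[2] < 0)) u <- -u
  half <- (geometry$majorLength - 1) / 2
  d <- c(ibCentroid[1] - geometry$centroid[1],
         ibCentroid[2] - geometry$centroid[2])
  p <- sum(d * u) / half
  list(position = max(-1, min(1, p)), degenerate = FALSE)
}

## provisional epoxy mask: everything well clear of any cell
.epoxyMaskFromCells <- function(cellLabels, marginPx = 3) {
  fg <- cellLabels > 0
  if (marginPx > 0)
    fg <- .em(EBImage::dilate(fg + 0, diskKernel(marginPx))) > 0
  !fg
}

#' Extract per-IB and per-cell feature tables
#'
#' Builds one record per inclusion body: geometry (area, equivalent radius,
#' polar position, pole proximity), beta-sheet ratios (mean 1625/1650 ratio
#' inside the IB and over the host cell's cytoplasm, and their quotient, the
#' beta-sheet enrichment), PLL stiffness contrast from the corrected
#' 1650 cm^-1 PLL map, raw amplitude means, and a thickness proxy (mean
#' height inside the IB minus the mean epoxy height). The cytoplasm of a
#' cell is its (eroded) mask minus all of its IB pixels; cells fully covered
#' by IBs have no cytoplasm and their IBs are flagged
#' (\code{cytoplasm_defined = FALSE}) with enrichment set to NA. A per-cell
#' summary (including cells with zero IBs) is returned alongside.
#'
#' @param pair A registered [DatasetPair-class].
#' @param seg A [SegmentationMaps-class].
#' @param pllMap Optional pre-corrected 1650 PLL [ChannelMap-class]; when
#'   NULL it is computed via [correctPllMap()] with a provisional epoxy mask
#'   derived from the cell labels.
#' @param minDenominatorQuantile Passed to [ratioMap()].
#' @return List with data.frames \code{ibs} and \code{cells}.
#' @export
extractIbFeatures <- function(pair, seg, pllMap = NULL,
                              minDenominatorQuantile = 0.01) {
  stopifnot(is(pair, "DatasetPair"), is(seg, "SegmentationMaps"))
  cl <- cellLabels(seg); il <- ibLabels(seg)
  pxNm <- pixelSizeNm(pair)
  amp25 <- getChannel(pair@ds1625, "IRAmplitude", "trace")
  amp50 <- getChannel(pair@ds1650, "IRAmplitude", "trace")
  epoxy <- .epoxyMaskFromCells(cl)
  rm0 <- ratioMap(amp25, amp50, minDenominatorQuantile, epoxyMask = epoxy)
  ratio <- mapData(rm0); rOk <- validMask(rm0)
  if (is.null(pllMap) && hasChannel(pair@ds1650, "PLLFrequency", "trace"))
    pllMap <- correctPllMap(getChannel(pair@ds1650, "PLLFrequency", "trace"),
                            epoxy)
  pll <- if (is.null(pllMap)) NULL
  else if (is(pllMap, "ChannelMap")) mapData(pllMap) else as.matrix(pllMap)
  height <- if (hasChannel(pair@ds1650, "Height", "trace"))
    mapData(getChannel(pair@ds1650, "Height", "trace")) else NULL
  heightEpoxy <- if (!is.null(height)) mean(height[epoxy]) else NA_real_

  own <- ibToCell(seg)
  cellIds <- setdiff(sort(unique(as.vector(cl))), 0L)
  ibRows <- list(); cellRows <- list()
  for (cid in cellIds) {
    cm <- cl == cid
    geom <- cellGeometry(cm)
    myIbs <- own$ib_id[own$cell_id == cid]
    cyto <- cm & il == 0L
    cytoOk <- cyto & rOk
    betaCp <- if (any(cytoOk)) mean(ratio[cytoOk]) else NA_real_
    pllCp <- if (!is.null(pll) && any(cyto)) mean(pll[cyto]) else NA_real_
    cellRows[[length(cellRows) + 1L]] <- data.frame(
      cell_id = cid, n_ibs = length(myIbs), cell_area_px = geom$area,
      cell_orientation = geom$orientation,
      cell_length_px = geom$majorLength,
      centroid_x = geom$centroid[1], centroid_y = geom$centroid[2],
      degenerate_orientation = geom$degenerate)
    for (ib in myIbs) {
      im <- il == ib
      a <- sum(im)
      idx <- which(im, arr.ind = TRUE)
      ctr <- c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)
      pp <- polarPosition(ctr, geom)
      imOk <- im & rOk
      betaIb <- if (any(imOk)) mean(ratio[imOk]) else NA_real_
      pllIb <- if (!is.null(pll)) mean(pll[im]) else NA_real_
      ibRows[[length(ibRows) + 1L]] <- data.frame(
        ib_id = ib, cell_id = cid,
        sample_id = sampleId(pair@ds1650),
        session_id = sessionId(pair@ds1650),
        area_px = a, area_nm2 = a * pxNm^2,
        equiv_radius_nm = sqrt(a / pi) * pxNm,
        polar_position = pp$position,
        pole_proximity = abs(pp$position),
        beta_ratio_ib = betaIb, beta_ratio_cp = betaCp,
        beta_enrichment = if (is.na(betaCp)) NA_real_ else betaIb / betaCp,
        cytoplasm_defined = !is.na(betaCp),
        pll_ib = pllIb, pll_cp = pllCp,
        pll_diff = pllIb - pllCp,
        amp_1625_mean = mean(mapData(amp25)[im & validMask(amp25)]),
        amp_1650_mean = mean(mapData(amp50)[im & validMask(amp50)]),
        height_mean = if (is.null(height)) NA_real_
                      else mean(height[im]) - heightEpoxy,
        cell_orientation = geom$orientation,
        cell_length_px = geom$majorLength,
        cell_area_px = geom$area)
    }
  }
  emptyIbs <- data.frame(
    ib_id = integer(), cell_id = integer(), sample_id = character(),
    session_id = character(), area_px = numeric(), area_nm2 = numeric(),
    equiv_radius_nm = numeric(), polar_position = numeric(),
    pole_proximity = numeric(), beta_ratio_ib = numeric(),
    beta_ratio_cp = numeric(), beta_enrichment = numeric(),
    cytoplasm_defined = logical(), pll_ib = numeric(), pll_cp = numeric(),
    pll_diff = numeric(), amp_1625_mean = numeric(),
    amp_1650_mean = numeric(), height_mean = numeric(),
    cell_orientation = numeric(), cell_length_px = numeric(),
    cell_area_px = numeric())
  ibs <- if (length(ibRows)) do.call(rbind, ibRows) else emptyIbs
  cells <- if (length(cellRows)) do.call(rbind, cellRows)
  else data.frame(cell_id = integer(), n_ibs = integer(),
                  cell_area_px = numeric(), cell_orientation = numeric(),
                  cell_length_px = numeric(), centroid_x = numeric(),
                  centroid_y = numeric(), degenerate_orientation = logical())
  rownames(ibs) <- NULL; rownames(cells) <- NULL
  list(ibs = ibs, cells = cells)
}

#' Signed-distance profile across IB boundaries
#'
#' Every pixel gets a signed Euclidean distance to the nearest IB boundary
#' (positive inside an IB, negative outside, via distance transforms of the
#' IB mask and its complement). Pixels are binned by distance; per bin the
#' mean 1625/1650 ratio and the mean corrected PLL are reported with
#' bootstrap percentile confidence intervals. Outside the IBs only cell
#' pixels contribute.
#'
#' @param pair A registered [DatasetPair-class].
#' @param seg A [SegmentationMaps-class] with at least one IB.
#' @param binWidthNm Distance bin width in nm (default: one pixel).
#' @param nBoot Bootstrap replicates per bin.
#' @param level Confidence level.
#' @param pllMap Optional pre-corrected PLL map (see
#'   [extractIbFeatures()]).
#' @param seed Seed for the bootstrap.
#' @return data.frame: bin centre (nm), n, mean_ratio with CI, mean_pll
#'   with CI.
#' @export
edgeDistanceProfile <- function(pair, seg, binWidthNm = NULL, nBoot = 999,
                                level = 0.95, pllMap = NULL, seed = 1L) {
  il <- ibLabels(seg); cl <- cellLabels(seg)
  if (!any(il > 0)) stop("no IBs in segmentation")
  pxNm <- pixelSizeNm(pair)
  if (is.null(binWidthNm)) binWidthNm <- pxNm
  ib <- il > 0
  dIn <- .em(EBImage::distmap(ib + 0))
  dOut <- .em(EBImage::distmap((!ib) + 0))
  signed <- (dIn - dOut) * pxNm
  amp25 <- getChannel(pair@ds1625, "IRAmplitude", "trace")
  amp50 <- getChannel(pair@ds1650, "IRAmplitude", "trace")
  epoxy <- .epoxyMaskFromCells(cl)
  rm0 <- ratioMap(amp25, amp50, epoxyMask = epoxy)
  if (is.null(pllMap) && hasChannel(pair@ds1650, "PLLFrequency", "trace"))
    pllMap <- correctPllMap(getChannel(pair@ds1650, "PLLFrequency", "trace"),
                            epoxy)
  pll <- if (is.null(pllMap)) NULL
  else if (is(pllMap, "ChannelMap")) mapData(pllMap) else as.matrix(pllMap)
  use <- (ib | cl > 0) & validMask(rm0)
  d <- signed[use]; rv <- mapData(rm0)[use]
  pv <- if (!is.null(pll)) pll[use] else NULL
  bins <- floor(d / binWidthNm)
  ub <- sort(unique(bins))
  .withSeed(seed, {
    rows <- lapply(ub, function(b) {
      i <- bins == b
      ci <- if (sum(i) >= 2) bootstrapCi(rv[i], nBoot = nBoot, level = level)
      else c(NA_real_, NA_real_)
      pci <- if (!is.null(pv) && sum(i) >= 2)
        bootstrapCi(pv[i], nBoot = nBoot, level = level)
      else c(NA_real_, NA_real_)
      data.frame(distance_nm = (b + 0.5) * binWidthNm, n = sum(i),
                 mean_ratio = mean(rv[i]), ratio_lo = ci[1], ratio_hi = ci[2],
                 mean_pll = if (is.null(pv)) NA_real_ else mean(pv[i]),
                 pll_lo = pci[1], pll_hi = pci[2])
    })
    do.call(rbind, rows)
  })
}

#' Fit a logistic transition to an edge profile
#'
#' Fits \code{lo + (hi - lo) / (1 + exp(-d / s))} to a signed-distance
#' profile and reports the boundary width as 4 sigma of the Gaussian edge
#' blur matched to the fitted logistic (sigma = 1.702 s), the convention
#' under which a sharp step blurred by a Gaussian of sigma has width
#' 4 sigma.
#'
#' @param profile data.frame from [edgeDistanceProfile()].
#' @param value Column to fit (default \code{"mean_ratio"}).
#' @return List: widthNm, scaleNm (logistic s), sigmaNm, fit (the nls
#'   object).
#' @export
fitEdgeWidth <- function(profile, value = "mean_ratio") {
  d <- profile$distance_nm; y <- profile[[value]]
  ok <- is.finite(d) & is.finite(y)
  d <- d[ok]; y <- y[ok]
  st <- list(lo = min(y), hi = max(y),
             s = max(diff(range(d)) / 20, 1e-3))
  fit <- stats::nls(y ~ lo + (hi - lo) / (1 + exp(-d / s)),
                    start = st,
                    control = stats::nls.control(maxiter = 200,
                                                 warnOnly = TRUE))
  s <- abs(stats::coef(fit)[["s"]])
  list(widthNm = 4 * 1.702 * s, scaleNm = s, sigmaNm = 1.702 * s, fit = fit)
}
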