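## Ground-truthed phantom scenes and synthetic band spectra.
##
## The phantom emulates the statistical structure the pipeline assumes --
## epoxy background, elliptical cell cross-sections with disk-shaped IBs,
## beta-sheet contrast between the 1625 and 1650 cm^-1 amplitude maps,
## diffuse IB edges, inter-map translation+shear drift, per-line PLL drift,
## an IB stiffness offset -- not the photothermal physics itself.

## fixed scene contrast levels (a.u. / kHz / nm); see the methods vignette
.PH <- list(
  epoxyAmp1650 = 0.5,   # epoxy amplitude at 1650 cm^-1
  cellAmp1650  = 1.0,   # cell (cytoplasm and IB) amplitude at 1650 cm^-1
  ratioCp      = 0.55,  # cytoplasm 1625/1650 ratio
  ratioBg      = 0.90,  # epoxy 1625/1650 ratio
  pllBaseKhz   = 880,   # contact-resonance pulse rate
  heightCellNm = 80,    # cell relief amplitude
  heightNoiseNm = 0.3,
  deflNoiseV   = 0.005,
  phaseNoiseDeg = 1.5
)

#' Generate a ground-truthed phantom dataset pair
#'
#' Builds a synthetic AFM-IR scene from a [PhantomSpec-class]: the reference
#' 1650 cm^-1 dataset samples the scene directly; the moving 1625 cm^-1
#' dataset samples it through the inverse of the true drift transform
#' (translation + scan shear applied to the later acquisition), so that
#' registration should recover exactly that transform. The scene is generated
#' with a padded margin and the moving acquisition samples the padded scene,
#' as a real drifting stage scans neighbouring sample -- no frame-edge voids.
#' Channel maps carry additive Gaussian noise; trace and retrace copies
#' differ by independent noise realisations. IB disks overlapping the cell
#' boundary are clipped to the cell and flagged in the ground truth.
#'
#' @param spec A [PhantomSpec-class].
#' @return A list with elements \code{pair} ([DatasetPair-class]) and
#'   \code{truth} ([GroundTruth-class]).
#' @examples
#' ph <- makePhantom(phantomSpec(imageSizePx = c(64L, 64L),
#'                               fieldOfViewUm = c(2.5, 2.5),
#'                               nCells = 1L, seed = 3L))
#' @export
makePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  .withSeed(spec@seed, .makePhantomImpl(spec))
}

.makePhantomImpl <- function(spec) {
  h <- spec@imageSizePx[1]; w <- spec@imageSizePx[2]
  pxNm <- 1000 * spec@fieldOfViewUm[1] / w
  drift <- spec@interMapDrift
  pad <- ceiling(max(abs(drift[1]) + abs(drift[3]) * h,
                     abs(drift[2]))) + 4L
  H <- h + 2L * pad; W <- w + 2L * pad

  ## --- place cells (padded-scene coordinates, 0-based) ---------------------
  cellLab <- matrix(0L, H, W)
  X <- matrix(rep(0:(W - 1), each = H), H, W)
  Y <- matrix(rep(0:(H - 1), times = W), H, W)
  cells <- list()
  nPlace <- spec@nCells + as.integer(spec@includeBorderCell)
  for (k in seq_len(nPlace)) {
    borderCell <- spec@includeBorderCell && k == nPlace
    placed <- FALSE
    for (try in 1:200) {
      a <- stats::runif(1, spec@cellMajorUm[1], spec@cellMajorUm[2]) *
        1000 / pxNm / 2
      b <- stats::runif(1, spec@cellMinorUm[1], spec@cellMinorUm[2]) *
        1000 / pxNm / 2
      phi <- stats::runif(1, 0, pi)
      if (borderCell) {
        if (H - pad - a <= pad + a) next
        cx <- pad + a * 0.3; cy <- stats::runif(1, pad + a, H - pad - a)
      } else {
        ## interior cells keep a 4 px clearance from the cropped frame so
        ## detection halos cannot graze the border
        if (W - pad - a - 5 <= pad + a + 4 || H - pad - a - 5 <= pad + a + 4)
          next                              # this draw cannot fit the frame
        cx <- stats::runif(1, pad + a + 4, W - pad - a - 5)
        cy <- stats::runif(1, pad + a + 4, H - pad - a - 5)
      }
      dxp <- X - cx; dyp <- Y - cy
      u <- dxp * cos(phi) + dyp * sin(phi)
      v <- -dxp * sin(phi) + dyp * cos(phi)
      inside <- (u / a)^2 + (v / b)^2 <= 1
      ## keep cells separated so instance segmentation is well-posed
      near <- (u / (a + 3))^2 + (v / (b + 3))^2 <= 1
      if (!borderCell && any(cellLab[near] > 0)) next
      cellLab[inside] <- k
      cells[[k]] <- list(cx = cx, cy = cy, a = a, b = b, phi = phi,
                         border = borderCell)
      placed <- TRUE
      break
    }
    if (!placed) {
      warning("could not place cell ", k, "; scene has fewer cells")
      cells[k] <- list(NULL)
    }
  }

  ## --- plant IB disks ------------------------------------------------------
  ibLab <- matrix(0L, H, W)
  ibRows <- list()
  ibId <- 0L
  for (k in seq_along(cells)) {
    ci <- cells[[k]]
    if (is.null(ci) || ci$border) next
    radii <- if (length(spec@ibRadiiPx)) spec@ibRadiiPx[[k]]
    else {
      nIb <- spec@ibCountRange[1] +
        sample.int(spec@ibCountRange[2] - spec@ibCountRange[1] + 1L, 1) - 1L
      if (nIb == 0) numeric() else
        stats::runif(nIb, spec@ibRadiusRangePx[1], spec@ibRadiusRangePx[2])
    }
    if (!length(radii)) next
    nIb <- length(radii)
    ux <- cos(ci$phi); uy <- sin(ci$phi)
    ts <- if (spec@ibPlacement == "spread" || nIb > 3) {
      seq(-0.6, 0.6, length.out = max(nIb, 2))[seq_len(nIb)]
    } else NULL
    for (j in seq_len(nIb)) {
      r <- radii[j]
      for (try in 1:100) {
        t <- if (!is.null(ts)) ts[j] else stats::runif(1, -0.7, 0.7)
        lat <- if (!is.null(ts)) 0 else
          stats::runif(1, -1, 1) * max(ci$b - r - 2, 0) * 0.5
        ## integer centres keep rasterised disks exactly matched to the
        ## Euclidean disk definition shared with the opening element
        icx <- round(ci$cx + t * ci$a * ux - lat * uy)
        icy <- round(ci$cy + t * ci$a * uy + lat * ux)
        disk <- (X - icx)^2 + (Y - icy)^2 <= r^2 + 1e-9
        ## keep IBs separated by > 2 px so connected components stay distinct
        near <- (X - icx)^2 + (Y - icy)^2 <= (r + 3)^2
        if (any(ibLab[near] > 0)) next
        inCell <- disk & cellLab == k
        if (!any(inCell)) next
        clipped <- sum(disk & cellLab != k) > 0
        ibId <- ibId + 1L
        ibLab[inCell] <- ibId
        sgn <- if (ux > 0 || (ux == 0 && uy > 0)) 1 else -1
        ibRows[[ibId]] <- data.frame(
          ib_id = ibId, cell_id = k,
          area_px = sum(inCell),
          equiv_radius_px = sqrt(sum(inCell) / pi),
          polar_position = max(-1, min(1, sgn * t)),
          enrichment = spec@betaEnrichmentTrue,
          pll_offset_khz = spec@pllOffsetIbKhz,
          clipped = clipped)
        break
      }
    }
  }
  ibTab <- if (length(ibRows)) do.call(rbind, ibRows) else
    data.frame(ib_id = integer(), cell_id = integer(), area_px = numeric(),
               equiv_radius_px = numeric(), polar_position = numeric(),
               enrichment = numeric(), pll_offset_khz = numeric(),
               clipped = logical())

  ## --- scene channels (padded frame) ---------------------------------------
  cellMask <- cellLab > 0
  ibMask <- ibLab > 0
  amp1650 <- matrix(.PH$epoxyAmp1650, H, W)
  amp1650[cellMask] <- .PH$cellAmp1650
  amp1625 <- matrix(.PH$epoxyAmp1650 * .PH$ratioBg, H, W)
  amp1625[cellMask] <- .PH$cellAmp1650 * .PH$ratioCp
  amp1625[ibMask] <- .PH$cellAmp1650 * .PH$ratioCp * spec@betaEnrichmentTrue
  if (spec@edgeBlurSigmaPx > 0) {
    ## the same PSF-like blur acts on both wavelength maps, so object
    ## boundaries are diffuse in both and the ratio map stays artefact-free
    amp1625 <- .em(EBImage::gblur(amp1625, sigma = spec@edgeBlurSigmaPx))
    amp1650 <- .em(EBImage::gblur(amp1650, sigma = spec@edgeBlurSigmaPx))
  }
  height <- matrix(0, H, W)
  for (k in seq_along(cells)) {
    ci <- cells[[k]]
    if (is.null(ci)) next
    dxp <- X - ci$cx; dyp <- Y - ci$cy
    u <- dxp * cos(ci$phi) + dyp * sin(ci$phi)
    v <- -dxp * sin(ci$phi) + dyp * cos(ci$phi)
    e <- (u / ci$a)^2 + (v / ci$b)^2
    dome <- .PH$heightCellNm * sqrt(pmax(0, 1 - e))
    height <- pmax(height, dome)
  }
  pll <- matrix(.PH$pllBaseKhz, H, W)
  pll[ibMask] <- .PH$pllBaseKhz + spec@pllOffsetIbKhz

  scene <- list(amp1650 = amp1650, amp1625 = amp1625, height = height,
                pll = pll)

  ## --- acquisition ---------------------------------------------------------
  crop <- function(m) m[(pad + 1):(pad + h), (pad + 1):(pad + w)]
  ## true transform in cropped-frame coordinates: x' = x + shear*y + dx
  Atrue <- affineShear(drift[3]) %*% affineTranslation(drift[1], drift[2])
  ## moving scene sampled through Atrue^-1, expressed in padded coordinates
  toPad <- affineTranslation(pad, pad)
  sampleScene <- function(m, M) {
    if (is.null(M)) return(crop(m))
    Mp <- toPad %*% M %*% solve(toPad)   # same transform in padded coords
    full <- .warpBilinear(m, solve(Mp))$data
    crop(full)
  }
  noisy <- function(m, sd) m + if (sd > 0) stats::rnorm(length(m), 0, sd) else 0
  acquire <- function(wn, M) {
    a <- if (abs(wn - 1650) < 1) scene$amp1650 else scene$amp1625
    ampS <- sampleScene(a, M)
    hS <- sampleScene(scene$height, M)
    pllS <- sampleScene(scene$pll, M)
    ramp <- spec@pllLineDrift[1] * (seq_len(h) - 1)
    chs <- list(
      ChannelMap("Height", noisy(hS, .PH$heightNoiseNm), "trace", "nm"),
      ChannelMap("Deflection", noisy(matrix(0, h, w), .PH$deflNoiseV),
                 "trace", "V"),
      ChannelMap("IRAmplitude", noisy(ampS, spec@amplitudeNoiseSd),
                 "trace", "a.u."),
      ChannelMap("IRAmplitude", noisy(ampS, spec@amplitudeNoiseSd),
                 "retrace", "a.u."),
      ChannelMap("PLLFrequency",
                 noisy(pllS + ramp, spec@pllLineDrift[2]), "trace", "kHz"),
      ChannelMap("PLLFrequency",
                 noisy(pllS + ramp, spec@pllLineDrift[2]), "retrace", "kHz"),
      ChannelMap("IRPhase", noisy(matrix(0, h, w), .PH$phaseNoiseDeg),
                 "trace", "deg"),
      ChannelMap("IRPhase", noisy(matrix(0, h, w), .PH$phaseNoiseDeg),
                 "retrace", "deg"))
    AFMIRDataset(wn, chs, spec@fieldOfViewUm,
                 sampleId = "phantom", sessionId = "phantom-session")
  }
  ds1650 <- acquire(1650, NULL)
  ds1625 <- acquire(1625, Atrue)

  truthCell <- crop(cellLab)
  truthIb <- crop(ibLab)
  ## relabel contiguously after cropping (border cell may be cut)
  reLab <- function(lab, tab = NULL) {
    ids <- sort(unique(as.vector(lab[lab > 0])))
    map <- integer(max(c(ids, 0L)))
    map[ids] <- seq_along(ids)
    lab[lab > 0] <- map[lab[lab > 0]]
    list(lab = lab, map = map, ids = ids)
  }
  rc <- reLab(truthCell); ri <- reLab(truthIb)
  keep <- ibTab$ib_id %in% ri$ids
  ibTab <- ibTab[keep, , drop = FALSE]
  if (nrow(ibTab)) {
    ibTab$ib_id <- ri$map[ibTab$ib_id]
    ibTab$cell_id <- rc$map[ibTab$cell_id]
    ibTab <- ibTab[order(ibTab$ib_id), , drop = FALSE]
    rownames(ibTab) <- NULL
  }
  truth <- new("GroundTruth", cellLabels = rc$lab, ibLabels = ri$lab,
               ibTable = ibTab, transform = Atrue)
  list(pair = DatasetPair(ds1650, ds1625), truth = truth)
}

## ---------------------------------------------------------------------------
## synthetic spectra
## ---------------------------------------------------------------------------

#' Amide-I band presets for synthetic spectra
#'
#' Gaussian band lists (center cm^-1, width sigma cm^-1, amplitude) for the
#' main spectral categories: cytoplasm (strong 1654 cm^-1 helix/disorder,
#' weak 1628 cm^-1 beta-sheet), inclusion body (strong beta-sheet), peroxide
#' stress (additional 1678 and 1616 cm^-1 beta-sheet bands) and an
#' illustrative epoxy background.
#'
#' @param preset One of \code{"CP"}, \code{"IB"}, \code{"peroxide"},
#'   \code{"BG"}.
#' @return Matrix with columns center, width, amplitude.
#' @export
bandPreset <- function(preset = c("CP", "IB", "peroxide", "BG")) {
  preset <- match.arg(preset)
  b <- switch(preset,
    CP = rbind(c(1654, 14, 1.0), c(1628, 10, 0.25)),
    IB = rbind(c(1654, 14, 1.0), c(1628, 10, 0.85)),
    peroxide = rbind(c(1654, 14, 1.0), c(1628, 10, 0.45),
                     c(1678, 8, 0.35), c(1616, 8, 0.30)),
    BG = rbind(c(1510, 30, 0.8), c(1240, 40, 0.9), c(1730, 18, 0.5),
               c(1180, 30, 0.6)))
  colnames(b) <- c("center", "width", "amplitude")
  b
}

#' Build a spectrum as a sum of Gaussian bands
#'
#' @param bands Matrix or data.frame with columns (center cm^-1,
#'   width sigma cm^-1, amplitude); an empty band list gives an all-zero
#'   spectrum. Alternatively a preset name accepted by [bandPreset()].
#' @param grid Wavenumber grid (cm^-1).
#' @param baseline Constant baseline added to the band sum.
#' @param noiseSd Additive Gaussian noise SD (0 = none).
#' @param ... Metadata passed to [Spectrum()] (category, sampleId, ...).
#' @return A [Spectrum-class].
#' @examples
#' s <- makeBandSpectrum(rbind(c(1625, 10, 1)), wavenumberGrid())
#' @export
makeBandSpectrum <- function(bands, grid = wavenumberGrid(), baseline = 0,
                             noiseSd = 0, ...) {
  if (is.character(bands)) bands <- bandPreset(bands)
  bands <- as.matrix(bands)
  amp <- rep(baseline, length(grid))
  if (nrow(bands)) {
    if (any(bands[, 2] <= 0))
      stop("band width must be positive")
    if (any(bands[, 1] < min(grid) | bands[, 1] > max(grid)))
      stop("band center outside grid")
    for (i in seq_len(nrow(bands)))
      amp <- amp + bands[i, 3] *
        exp(-0.5 * ((grid - bands[i, 1]) / bands[i, 2])^2)
  }
  if (noiseSd > 0) amp <- amp + stats::rnorm(length(amp), 0, noiseSd)
  Spectrum(grid, amp, ...)
}
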