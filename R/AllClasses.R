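#' @import methods
NULL

.CHANNELS <- c("Height", "Deflection", "IRAmplitude", "PLLFrequency",
               "IRPhase", "Ratio")
.DIRECTIONS <- c("trace", "retrace")
.CATEGORIES <- c("IB", "CP", "BG")

## ---------------------------------------------------------------------------
## Wavenumber grid
## ---------------------------------------------------------------------------

#' Construct a wavenumber grid
#'
#' A wavenumber grid is a strictly increasing, uniformly spaced numeric vector
#' of wavenumbers in cm^-1. The acquisition default covers the 800-1800 cm^-1
#' range at 2 cm^-1 spectral resolution (501 points).
#'
#' @param from,to Range endpoints in cm^-1 (inclusive).
#' @param by Step in cm^-1.
#' @return Numeric vector of wavenumbers.
#' @examples
#' g <- wavenumberGrid()
#' length(g)  # 501
#' @export
wavenumberGrid <- function(from = 800, to = 1800, by = 2) {
  g <- seq(from, to, by = by)
  .checkWavenumberGrid(g)
  g
}

.checkWavenumberGrid <- function(g) {
  if (length(g) < 2L)
    stop("wavenumber grid must have at least 2 points")
  d <- diff(g)
  if (any(d <= 0))
    stop("wavenumber grid must be strictly increasing")
  if (max(d) - min(d) > 1e-8 * mean(d))
    stop("wavenumber grid must be uniformly spaced")
  invisible(TRUE)
}

## ---------------------------------------------------------------------------
## Spectrum
## ---------------------------------------------------------------------------

#' Spectrum: a wavenumber-indexed AFM-IR point spectrum
#'
#' Holds the IR amplitude channel (assumed already normalised with respect to
#' the laser emission spectrum), an optional parallel PLL frequency channel
#' (kHz), a validity mask, and acquisition metadata. The category records
#' where the spectrum was taken: \code{"IB"} (inclusion body), \code{"CP"}
#' (cytoplasm) or \code{"BG"} (epoxy background).
#'
#' @slot wavenumber Numeric wavenumber grid (cm^-1), see [wavenumberGrid()].
#' @slot irAmplitude Numeric IR amplitude, same length as the grid (a.u.).
#' @slot pllFrequency Numeric PLL frequency (kHz), same length as the grid,
#'   or length zero when the channel was not recorded.
#' @slot valid Logical validity mask (TRUE = usable point).
#' @slot sampleId,sessionId Character scalars identifying sample and
#'   measurement session.
#' @slot category One of \code{"IB"}, \code{"CP"}, \code{"BG"}.
#' @slot position Numeric (x, y) position in micrometres from the top-left
#'   map corner, or length zero when unknown.
#' @export
setClass("Spectrum",
  representation(
    wavenumber   = "numeric",
    irAmplitude  = "numeric",
    pllFrequency = "numeric",
    valid        = "logical",
    sampleId     = "character",
    sessionId    = "character",
    category     = "character",
    position     = "numeric"
  )
)

setValidity("Spectrum", function(object) {
  msg <- character()
  g <- object@wavenumber
  v <- tryCatch({ .checkWavenumberGrid(g); NULL }, error = conditionMessage)
  if (!is.null(v)) msg <- c(msg, v)
  n <- length(g)
  if (length(object@irAmplitude) != n)
    msg <- c(msg, "irAmplitude length must equal grid length")
  if (length(object@pllFrequency) > 0L && length(object@pllFrequency) != n)
    msg <- c(msg, "pllFrequency length must equal grid length")
  if (length(object@valid) != n)
    msg <- c(msg, "valid mask length must equal grid length")
  if (any(object@valid & !is.finite(object@irAmplitude)))
    msg <- c(msg, "irAmplitude must be finite at valid points")
  if (length(object@category) != 1L || !object@category %in% .CATEGORIES)
    msg <- c(msg, "category must be one of IB, CP, BG")
  if (!length(object@position) %in% c(0L, 2L))
    msg <- c(msg, "position must be numeric(0) or (x, y) in um")
  if (length(msg)) msg else TRUE
})

#' @rdname Spectrum-class
#' @param wavenumber,irAmplitude,pllFrequency,valid,sampleId,sessionId,category,position
#'   See the corresponding slots.
#' @return A \code{Spectrum} object.
#' @examples
#' s <- Spectrum(wavenumberGrid(), rep(1, 501), category = "BG")
#' @export
Spectrum <- function(wavenumber, irAmplitude, pllFrequency = numeric(),
                     valid = NULL, sampleId = "", sessionId = "",
                     category = "CP", position = numeric()) {
  if (is.null(valid)) valid <- is.finite(irAmplitude)
  new("Spectrum", wavenumber = as.numeric(wavenumber),
      irAmplitude = as.numeric(irAmplitude),
      pllFrequency = as.numeric(pllFrequency), valid = valid,
      sampleId = sampleId, sessionId = sessionId, category = category,
      position = as.numeric(position))
}

## ---------------------------------------------------------------------------
## ChannelMap
## ---------------------------------------------------------------------------

#' ChannelMap: one 2D data channel of an AFM-IR acquisition
#'
#' A rectangular raster of one acquired channel in one scanning direction.
#' Pixels are stored row-major with the origin at the top-left corner; row r,
#' column c corresponds to pixel coordinates (x, y) = (c - 1, r - 1).
#' Invalid pixels are flagged in an explicit boolean validity map rather than
#' encoded as sentinel values.
#'
#' @slot channel One of Height, Deflection, IRAmplitude, PLLFrequency,
#'   IRPhase, or Ratio (for derived ratio maps).
#' @slot direction Scanning direction, \code{"trace"} or \code{"retrace"}.
#' @slot data Numeric matrix (rows = scan lines).
#' @slot units Character scalar (nm, V, a.u., kHz, deg, ...).
#' @slot valid Logical matrix of the same shape.
#' @export
setClass("ChannelMap",
  representation(
    channel   = "character",
    direction = "character",
    data      = "matrix",
    units     = "character",
    valid     = "matrix"
  )
)

setValidity("ChannelMap", function(object) {
  msg <- character()
  if (!object@channel %in% .CHANNELS)
    msg <- c(msg, paste("channel must be one of:",
                        paste(.CHANNELS, collapse = ", ")))
  if (!object@direction %in% .DIRECTIONS)
    msg <- c(msg, "direction must be 'trace' or 'retrace'")
  if (!identical(dim(object@data), dim(object@valid)))
    msg <- c(msg, "data and valid mask must share shape")
  if (any(object@valid & !is.finite(object@data)))
    msg <- c(msg, "data must be finite wherever valid")
  if (length(msg)) msg else TRUE
})

#' @rdname ChannelMap-class
#' @param channel,data,direction,units,valid See the corresponding slots.
#' @return A \code{ChannelMap}.
#' @export
ChannelMap <- function(channel, data, direction = "trace", units = "",
                       valid = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(valid)) valid <- is.finite(data)
  new("ChannelMap", channel = channel, direction = direction, data = data,
      units = units, valid = valid)
}

## ---------------------------------------------------------------------------
## AFMIRDataset
## ---------------------------------------------------------------------------

#' AFMIRDataset: co-acquired channel maps at one illumination wavenumber
#'
#' Bundles all channel maps recorded simultaneously at a single laser
#' wavenumber, with the pixel geometry and session metadata. All maps must
#' share one shape, and the pixel geometry must satisfy
#' \code{pixelSizeNm * width_px == 1000 * fieldOfViewUm[1]}.
#'
#' @slot wavenumber Illumination wavenumber in cm^-1.
#' @slot channels List of [ChannelMap-class] objects (unique
#'   channel/direction combinations).
#' @slot pixelSizeNm Pixel size in nm.
#' @slot fieldOfViewUm Numeric (width, height) in micrometres.
#' @slot sampleId,sessionId Character metadata.
#' @export
setClass("AFMIRDataset",
  representation(
    wavenumber    = "numeric",
    channels      = "list",
    pixelSizeNm   = "numeric",
    fieldOfViewUm = "numeric",
    sampleId      = "character",
    sessionId     = "character"
  )
)

setValidity("AFMIRDataset", function(object) {
  msg <- character()
  if (length(object@wavenumber) != 1L ||
      object@wavenumber < 800 || object@wavenumber > 1800)
    msg <- c(msg, "wavenumber must be a scalar within 800-1800 cm^-1")
  if (!length(object@channels))
    msg <- c(msg, "dataset must contain at least one channel map")
  ok <- vapply(object@channels, is, logical(1), class2 = "ChannelMap")
  if (!all(ok)) {
    msg <- c(msg, "channels must be ChannelMap objects")
  } else {
    dims <- vapply(object@channels, function(ch) dim(ch@data), integer(2))
    if (length(object@channels) > 1L && any(dims != dims[, 1]))
      msg <- c(msg, "all channel maps must share shape")
    key <- vapply(object@channels,
                  function(ch) paste(ch@channel, ch@direction, sep = "/"),
                  character(1))
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate channel/direction combination")
    wpx <- dims[2, 1]
    geom <- object@pixelSizeNm * wpx - 1000 * object@fieldOfViewUm[1]
    if (abs(geom) > 1e-6 * 1000 * object@fieldOfViewUm[1])
      msg <- c(msg,
        "geometry violated: pixelSizeNm * width_px must equal 1000 * field width (um)")
  }
  if (length(object@fieldOfViewUm) != 2L || any(object@fieldOfViewUm <= 0))
    msg <- c(msg, "fieldOfViewUm must be positive (width, height)")
  if (length(msg)) msg else TRUE
})

#' @rdname AFMIRDataset-class
#' @param wavenumber,channels,fieldOfViewUm,sampleId,sessionId See slots.
#' @param pixelSizeNm Pixel size in nm; derived from the field of view and
#'   map width when omitted.
#' @return An \code{AFMIRDataset}.
#' @export
AFMIRDataset <- function(wavenumber, channels, fieldOfViewUm,
                         pixelSizeNm = NULL, sampleId = "", sessionId = "") {
  if (is.null(pixelSizeNm)) {
    wpx <- ncol(channels[[1]]@data)
    pixelSizeNm <- 1000 * fieldOfViewUm[1] / wpx
  }
  new("AFMIRDataset", wavenumber = wavenumber, channels = channels,
      pixelSizeNm = pixelSizeNm, fieldOfViewUm = as.numeric(fieldOfViewUm),
      sampleId = sampleId, sessionId = sessionId)
}

## ---------------------------------------------------------------------------
## DatasetPair
## ---------------------------------------------------------------------------

#' DatasetPair: the 1650/1625 cm^-1 acquisition pair
#'
#' The reference dataset is acquired at 1650 cm^-1 (alpha-helix/disordered
#' amide I) and the moving dataset at 1625 cm^-1 (beta-sheet amide I). The
#' later 1625 scan accumulates stage drift; [registerPair()] estimates the
#' pixel-coordinate affine transform mapping reference coordinates to moving
#' coordinates and resamples the 1625 channels onto the reference frame. The
#' transform slot holds that 3x3 matrix (last row 0, 0, 1) or a 0x0 matrix
#' while unregistered.
#'
#' @slot ds1650 Reference [AFMIRDataset-class] at 1650 cm^-1.
#' @slot ds1625 Moving [AFMIRDataset-class] at 1625 cm^-1.
#' @slot transform 3x3 affine matrix in pixel coordinates, or 0x0 if unset.
#' @export
setClass("DatasetPair",
  representation(ds1650 = "AFMIRDataset", ds1625 = "AFMIRDataset",
                 transform = "matrix")
)

setValidity("DatasetPair", function(object) {
  msg <- character()
  if (abs(object@ds1650@wavenumber - 1650) > 1e-6 ||
      abs(object@ds1625@wavenumber - 1625) > 1e-6)
    msg <- c(msg, "pair must hold a 1650 (reference) and a 1625 (moving) dataset")
  d1 <- dim(object@ds1650@channels[[1]]@data)
  d2 <- dim(object@ds1625@channels[[1]]@data)
  if (!identical(d1, d2))
    msg <- c(msg, "datasets must share shape")
  if (abs(object@ds1650@pixelSizeNm - object@ds1625@pixelSizeNm) > 1e-6)
    msg <- c(msg, "datasets must share pixel size")
  tr <- object@transform
  if (length(tr) && (!identical(dim(tr), c(3L, 3L)) ||
                     any(abs(tr[3, ] - c(0, 0, 1)) > 1e-9)))
    msg <- c(msg, "transform must be 3x3 with last row (0, 0, 1)")
  if (length(tr) && abs(det(tr)) < 1e-12)
    msg <- c(msg, "transform must be invertible")
  if (length(msg)) msg else TRUE
})

#' @rdname DatasetPair-class
#' @param ds1650,ds1625 The two datasets.
#' @param transform Optional 3x3 affine matrix (pixel coordinates).
#' @return A \code{DatasetPair}.
#' @export
DatasetPair <- function(ds1650, ds1625, transform = NULL) {
  if (is.null(transform)) transform <- matrix(numeric(), 0, 0)
  new("DatasetPair", ds1650 = ds1650, ds1625 = ds1625, transform = transform)
}

## ---------------------------------------------------------------------------
## SegmentationMaps
## ---------------------------------------------------------------------------

#' SegmentationMaps: cell and inclusion-body label maps
#'
#' Instance label maps for cells and IBs (0 = background / none) plus the
#' IB-to-cell ownership table. Invariants: every IB pixel lies on a cell
#' pixel, no cell label touches the image border (border-intersecting cells
#' are discarded upstream), and label ids are contiguous from 1.
#'
#' @slot cellLabels Integer matrix of cell instance labels.
#' @slot ibLabels Integer matrix of IB instance labels.
#' @slot ibToCell data.frame with columns \code{ib_id}, \code{cell_id}.
#' @export
setClass("SegmentationMaps",
  representation(cellLabels = "matrix", ibLabels = "matrix",
                 ibToCell = "data.frame")
)

setValidity("SegmentationMaps", function(object) {
  msg <- character()
  cl <- object@cellLabels; il <- object@ibLabels
  if (!identical(dim(cl), dim(il)))
    msg <- c(msg, "label maps must share shape")
  if (any(il > 0 & cl == 0))
    msg <- c(msg, "every IB pixel must lie on a cell pixel")
  border <- c(cl[1, ], cl[nrow(cl), ], cl[, 1], cl[, ncol(cl)])
  if (any(border > 0))
    msg <- c(msg, "no cell label may touch the image border")
  for (nm in c("cellLabels", "ibLabels")) {
    lab <- slot(object, nm)
    ids <- sort(unique(as.vector(lab[lab > 0])))
    if (length(ids) && !identical(as.integer(ids), seq_along(ids)))
      msg <- c(msg, paste(nm, "ids must be contiguous from 1"))
  }
  if (!all(c("ib_id", "cell_id") %in% names(object@ibToCell)))
    msg <- c(msg, "ibToCell needs columns ib_id, cell_id")
  if (length(msg)) msg else TRUE
})

#' @rdname SegmentationMaps-class
#' @param cellLabels,ibLabels,ibToCell See slots.
#' @return A \code{SegmentationMaps}.
#' @export
SegmentationMaps <- function(cellLabels, ibLabels = NULL, ibToCell = NULL) {
  cellLabels <- .asLabelMatrix(cellLabels)
  if (is.null(ibLabels))
    ibLabels <- matrix(0L, nrow(cellLabels), ncol(cellLabels))
  ibLabels <- .asLabelMatrix(ibLabels)
  if (is.null(ibToCell))
    ibToCell <- data.frame(ib_id = integer(), cell_id = integer())
  new("SegmentationMaps", cellLabels = cellLabels, ibLabels = ibLabels,
      ibToCell = ibToCell)
}

.asLabelMatrix <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  m
}

## ---------------------------------------------------------------------------
## PhantomSpec / GroundTruth
## ---------------------------------------------------------------------------

#' PhantomSpec: full parameterisation of a synthetic AFM-IR scene
#'
#' Describes a ground-truthed phantom emulating an epoxy-embedded bacterial
#' section: elliptical cell cross-sections with disk-shaped inclusion bodies,
#' beta-sheet contrast between the 1625 and 1650 cm^-1 amplitude maps,
#' optionally diffuse IB edges, inter-map drift (translation plus shear of
#' the later 1625 scan), per-line PLL frequency drift, an IB stiffness (PLL)
#' offset, and additive Gaussian channel noise. Defaults reproduce the
#' acquisition geometry of a 20 x 20 um, 512 x 512 px map (39 nm pixels) and
#' biologically plausible contrast levels; see the package vignette.
#'
#' @slot imageSizePx Integer (height, width) in pixels.
#' @slot fieldOfViewUm Numeric (width, height) in micrometres.
#' @slot nCells Number of cells to place.
#' @slot cellMajorUm,cellMinorUm Ranges (min, max) of cell full axis lengths
#'   in micrometres.
#' @slot ibRadiiPx List with one numeric vector of IB radii (px) per cell;
#'   empty list = draw counts and radii at random from \code{ibCountRange}
#'   and \code{ibRadiusRangePx}.
#' @slot ibCountRange Integer range of IBs per cell.
#' @slot ibRadiusRangePx Numeric range of IB radii in pixels.
#' @slot ibPlacement \code{"random"} or \code{"spread"} (evenly spaced along
#'   the cell major axis).
#' @slot betaEnrichmentTrue True ratio of the IB 1625/1650 amplitude ratio to
#'   the cytoplasmic one.
#' @slot edgeBlurSigmaPx Gaussian sigma (px) blurring the 1625 amplitude
#'   scene, making IB boundaries diffuse; 0 = sharp edges.
#' @slot pllOffsetIbKhz Planted PLL frequency offset inside IBs (kHz).
#' @slot pllLineDrift Numeric (slope kHz/line, per-pixel noise SD kHz) of the
#'   PLL channel.
#' @slot interMapDrift Numeric (dx px, dy px, shear fraction) applied to the
#'   1625 acquisition.
#' @slot amplitudeNoiseSd Additive Gaussian noise SD on IR amplitude maps.
#' @slot includeBorderCell Also place one cell intersecting the image border
#'   (it must be discarded by segmentation).
#' @slot seed Integer random seed; a fixed seed gives identical output.
#' @export
setClass("PhantomSpec",
  representation(
    imageSizePx      = "integer",
    fieldOfViewUm    = "numeric",
    nCells           = "integer",
    cellMajorUm      = "numeric",
    cellMinorUm      = "numeric",
    ibRadiiPx        = "list",
    ibCountRange     = "integer",
    ibRadiusRangePx  = "numeric",
    ibPlacement      = "character",
    betaEnrichmentTrue = "numeric",
    edgeBlurSigmaPx  = "numeric",
    pllOffsetIbKhz   = "numeric",
    pllLineDrift     = "numeric",
    interMapDrift    = "numeric",
    amplitudeNoiseSd = "numeric",
    includeBorderCell = "logical",
    seed             = "integer"
  ),
  prototype(
    imageSizePx      = c(512L, 512L),
    fieldOfViewUm    = c(20, 20),
    nCells           = 12L,
    cellMajorUm      = c(1.2, 2.6),
    cellMinorUm      = c(0.55, 0.95),
    ibRadiiPx        = list(),
    ibCountRange     = c(0L, 3L),
    ibRadiusRangePx  = c(2, 6),
    ibPlacement      = "random",
    betaEnrichmentTrue = 1.15,
    edgeBlurSigmaPx  = 0.8,
    pllOffsetIbKhz   = 0.35,
    pllLineDrift     = c(slope = 2e-3, noiseSd = 0.05),
    interMapDrift    = c(dx = 4, dy = -3, shear = 0.01),
    amplitudeNoiseSd = 0.02,
    includeBorderCell = FALSE,
    seed             = 1L
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@imageSizePx) != 2L || any(object@imageSizePx < 16L))
    msg <- c(msg, "imageSizePx must be (height, width), each >= 16")
  if (any(object@fieldOfViewUm <= 0))
    msg <- c(msg, "fieldOfViewUm must be positive")
  if (object@nCells < 0L) msg <- c(msg, "nCells must be >= 0")
  if (length(object@ibRadiiPx) &&
      length(object@ibRadiiPx) != object@nCells)
    msg <- c(msg, "ibRadiiPx must list radii for every cell")
  if (!object@ibPlacement %in% c("random", "spread"))
    msg <- c(msg, "ibPlacement must be 'random' or 'spread'")
  if (object@betaEnrichmentTrue <= 0)
    msg <- c(msg, "betaEnrichmentTrue must be positive")
  if (object@edgeBlurSigmaPx < 0 || object@amplitudeNoiseSd < 0)
    msg <- c(msg, "noise and blur parameters must be non-negative")
  if (length(object@interMapDrift) != 3L)
    msg <- c(msg, "interMapDrift must be (dx, dy, shear)")
  if (length(object@pllLineDrift) != 2L || object@pllLineDrift[2] < 0)
    msg <- c(msg, "pllLineDrift must be (slope, noise SD >= 0)")
  if (length(msg)) msg else TRUE
})

#' @rdname PhantomSpec-class
#' @param ... Slot values overriding the defaults (see slots).
#' @return A \code{PhantomSpec}.
#' @examples
#' spec <- phantomSpec(imageSizePx = c(96L, 96L), nCells = 3L, seed = 7L)
#' @export
phantomSpec <- function(...) {
  args <- list(...)
  for (nm in c("imageSizePx", "nCells", "ibCountRange", "seed"))
    if (!is.null(args[[nm]])) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("PhantomSpec"), args))
}

#' GroundTruth: the known answer behind a phantom
#'
#' Label maps, per-IB true features and the true inter-map transform of a
#' scene produced by [makePhantom()]. Label maps live in the reference
#' (1650 cm^-1) frame.
#'
#' @slot cellLabels,ibLabels Integer label maps.
#' @slot ibTable data.frame of true per-IB features: ib_id, cell_id, area_px,
#'   equiv_radius_px, polar_position, enrichment, pll_offset_khz, clipped.
#' @slot transform True 3x3 transform mapping reference pixel coordinates to
#'   moving (1625) pixel coordinates.
#' @export
setClass("GroundTruth",
  representation(cellLabels = "matrix", ibLabels = "matrix",
                 ibTable = "data.frame", transform = "matrix")
)

## ---------------------------------------------------------------------------
## StatTestReport
## ---------------------------------------------------------------------------

#' StatTestReport: record of the test-selection decision tree
#'
#' Produced by [chooseAndRunTest()]. Records the pre-tests (Shapiro normality
#' per group, Bartlett homoscedasticity), the chosen omnibus test, its result,
#' and the post hoc pairwise table. Bonferroni-adjusted p values are uncapped
#' by default (values above 1 are reported as such); the number of
#' comparisons used for each adjustment is recorded so corrections are never
#' silently stacked.
#'
#' @slot groups Group labels.
#' @slot sizes Group sizes.
#' @slot normalityP,normalityPAdj Shapiro p values per group (raw, adjusted).
#' @slot homoscedasticityP,homoscedasticityPAdj Bartlett p value (raw,
#'   adjusted).
#' @slot pretestCorrection Correction applied to the pre-test family.
#' @slot alphaPretest Pre-test significance level.
#' @slot chosenTest \code{"ANOVA"} or \code{"Kruskal-Wallis"}.
#' @slot statistic,p Omnibus statistic and p value.
#' @slot posthocMethod Post hoc method used (or \code{"none"}).
#' @slot posthoc data.frame of pairwise comparisons with p and p_adj.
#' @slot mPosthoc Number of comparisons behind the post hoc adjustment.
#' @export
setClass("StatTestReport",
  representation(
    groups = "character", sizes = "integer",
    normalityP = "numeric", normalityPAdj = "numeric",
    homoscedasticityP = "numeric", homoscedasticityPAdj = "numeric",
    pretestCorrection = "character", alphaPretest = "numeric",
    chosenTest = "character", statistic = "numeric", p = "numeric",
    posthocMethod = "character", posthoc = "data.frame",
    mPosthoc = "integer"
  )
)

#' CorrelationMatrixResult: bootstrap-tested property correlations
#'
#' Produced by [correlationMatrixBootstrap()]. Pearson correlations are
#' computed per dataset for every property pair; the resulting set of
#' correlations per pair is bootstrap-resampled to test whether its mean
#' differs from zero, with Bonferroni correction over the number of pairs.
#'
#' @slot vars Property names.
#' @slot meanR Mean correlation per pair (symmetric matrix).
#' @slot p,pAdj Raw and Bonferroni-adjusted (uncapped) bootstrap p values.
#' @slot significant Logical matrix: \code{pAdj < alpha}.
#' @slot rValues data.frame of per-dataset correlations (pair x dataset).
#' @slot nBoot,alpha Bootstrap replicates and significance level used.
#' @export
setClass("CorrelationMatrixResult",
  representation(vars = "character", meanR = "matrix", p = "matrix",
                 pAdj = "matrix", significant = "matrix",
                 rValues = "data.frame", nBoot = "integer", alpha = "numeric")
)
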