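#' @include AllGenerics.R
NULL

## Spectrum accessors ---------------------------------------------------------

#' @rdname accessors
setMethod("wavenumber", "Spectrum", function(object, ...) object@wavenumber)

#' @rdname accessors
setMethod("irAmplitude", "Spectrum", function(object, ...) object@irAmplitude)

#' @rdname accessors
setMethod("pllFrequency", "Spectrum", function(object, ...) {
  if (!length(object@pllFrequency)) NULL else object@pllFrequency
})

#' @rdname accessors
setMethod("validMask", "Spectrum", function(object, ...) object@valid)

#' @rdname accessors
setMethod("category", "Spectrum", function(object, ...) object@category)

#' @rdname accessors
setMethod("sampleId", "Spectrum", function(object, ...) object@sampleId)

#' @rdname accessors
setMethod("sessionId", "Spectrum", function(object, ...) object@sessionId)

setMethod("show", "Spectrum", function(object) {
  g <- object@wavenumber
  cat(sprintf("Spectrum [%s] %d points, %.0f-%.0f cm^-1 (step %.1f)\n",
              object@category, length(g), min(g), max(g), g[2] - g[1]))
  cat(sprintf("  sample '%s', session '%s', PLL channel: %s, %d masked\n",
              object@sampleId, object@sessionId,
              if (length(object@pllFrequency)) "yes" else "no",
              sum(!object@valid)))
})

## ChannelMap -----------------------------------------------------------------

#' @rdname accessors
setMethod("mapData", "ChannelMap", function(object, ...) object@data)

#' @rdname accessors
setMethod("validMask", "ChannelMap", function(object, ...) object@valid)

#' @rdname accessors
setMethod("category", "ChannelMap", function(object, ...) object@channel)

setMethod("show", "ChannelMap", function(object) {
  cat(sprintf("ChannelMap %s/%s %dx%d px [%s], %d invalid px\n",
              object@channel, object@direction, nrow(object@data),
              ncol(object@data), object@units, sum(!object@valid)))
})

## AFMIRDataset ---------------------------------------------------------------

#' @rdname accessors
setMethod("wavenumber", "AFMIRDataset", function(object, ...) object@wavenumber)

#' @rdname accessors
setMethod("pixelSizeNm", "AFMIRDataset", function(object, ...) object@pixelSizeNm)

#' @rdname accessors
setMethod("fieldOfViewUm", "AFMIRDataset",
          function(object, ...) object@fieldOfViewUm)

#' @rdname accessors
setMethod("sampleId", "AFMIRDataset", function(object, ...) object@sampleId)

#' @rdname accessors
setMethod("sessionId", "AFMIRDataset", function(object, ...) object@sessionId)

.channelKey <- function(ds) {
  vapply(ds@channels,
         function(ch) paste(ch@channel, ch@direction, sep = "/"),
         character(1))
}

#' @rdname getChannel
setMethod("hasChannel", "AFMIRDataset",
  function(object, channel, direction = "trace") {
    paste(channel, direction, sep = "/") %in% .channelKey(object)
  })

#' @rdname getChannel
setMethod("getChannel", "AFMIRDataset",
  function(object, channel, direction = "trace") {
    key <- paste(channel, direction, sep = "/")
    i <- match(key, .channelKey(object))
    if (is.na(i))
      stop("missing channel: ", key)
    object@channels[[i]]
  })

## replace or add a channel map (internal)
.setChannel <- function(ds, cm) {
  key <- paste(cm@channel, cm@direction, sep = "/")
  i <- match(key, .channelKey(ds))
  if (is.na(i)) ds@channels <- c(ds@channels, list(cm))
  else ds@channels[[i]] <- cm
  ds
}

setMethod("show", "AFMIRDataset", function(object) {
  d <- dim(object@channels[[1]]@data)
  cat(sprintf("AFMIRDataset @ %.0f cm^-1, %dx%d px, %.1f nm/px (%g x %g um)\n",
              object@wavenumber, d[1], d[2], object@pixelSizeNm,
              object@fieldOfViewUm[1], object@fieldOfViewUm[2]))
  cat("  channels:", paste(.channelKey(object), collapse = ", "), "\n")
})

## DatasetPair ----------------------------------------------------------------

#' @rdname accessors
setMethod("pairTransform", "DatasetPair", function(object, ...) {
  if (!length(object@transform)) NULL else object@transform
})

#' @rdname accessors
setMethod("isRegistered", "DatasetPair",
          function(object, ...) length(object@transform) > 0L)

#' @rdname accessors
setMethod("pixelSizeNm", "DatasetPair",
          function(object, ...) object@ds1650@pixelSizeNm)

setMethod("show", "DatasetPair", function(object) {
  cat("DatasetPair (1650 reference / 1625 moving)\n")
  show(object@ds1650); show(object@ds1625)
  if (isRegistered(object)) {
    tr <- object@transform
    cat(sprintf("  registered: translation (%.2f, %.2f) px\n",
                tr[1, 3], tr[2, 3]))
  } else cat("  not registered\n")
})

## SegmentationMaps -----------------------------------------------------------

#' @rdname accessors
setMethod("cellLabels", "SegmentationMaps", function(object, ...) object@cellLabels)

#' @rdname accessors
setMethod("ibLabels", "SegmentationMaps", function(object, ...) object@ibLabels)

#' @rdname accessors
setMethod("ibToCell", "SegmentationMaps", function(object, ...) object@ibToCell)

setMethod("show", "SegmentationMaps", function(object) {
  cat(sprintf("SegmentationMaps %dx%d px: %d cells, %d IBs\n",
              nrow(object@cellLabels), ncol(object@cellLabels),
              max(object@cellLabels), max(object@ibLabels)))
})

## GroundTruth ----------------------------------------------------------------

#' @rdname accessors
setMethod("cellLabels", "GroundTruth", function(object, ...) object@cellLabels)

#' @rdname accessors
setMethod("ibLabels", "GroundTruth", function(object, ...) object@ibLabels)

#' @rdname accessors
setMethod("ibTable", "GroundTruth", function(object, ...) object@ibTable)

#' @rdname accessors
setMethod("trueTransform", "GroundTruth", function(object, ...) object@transform)

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d cells, %d IBs, drift (%.2f, %.2f) px\n",
              max(object@cellLabels), nrow(object@ibTable),
              object@transform[1, 3], object@transform[2, 3]))
})

## PhantomSpec ----------------------------------------------------------------

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec %dx%d px (%g x %g um), %d cells, enrichment %.2f, seed %d\n",
    object@imageSizePx[1], object@imageSizePx[2], object@fieldOfViewUm[1],
    object@fieldOfViewUm[2], object@nCells, object@betaEnrichmentTrue,
    object@seed))
  cat(sprintf("  drift (%.1f, %.1f) px, shear %.3f; blur sigma %.2f px; noise SD %.3f\n",
              object@interMapDrift[1], object@interMapDrift[2],
              object@interMapDrift[3], object@edgeBlurSigmaPx,
              object@amplitudeNoiseSd))
})

## StatTestReport -------------------------------------------------------------

#' @rdname accessors
setMethod("chosenTest", "StatTestReport", function(object, ...) object@chosenTest)

#' @rdname accessors
setMethod("posthocTable", "StatTestReport", function(object, ...) object@posthoc)

setMethod("show", "StatTestReport", function(object) {
  cat("StatTestReport\n")
  cat(sprintf("  groups: %s (n = %s)\n",
              paste(object@groups, collapse = ", "),
              paste(object@sizes, collapse = ", ")))
  cat(sprintf("  Shapiro p (adj, %s): %s\n", object@pretestCorrection,
              paste(signif(object@normalityPAdj, 3), collapse = ", ")))
  cat(sprintf("  Bartlett p (adj): %s\n",
              signif(object@homoscedasticityPAdj, 3)))
  cat(sprintf("  chosen test: %s, statistic = %.4g, p = %.4g\n",
              object@chosenTest, object@statistic, object@p))
  if (object@posthocMethod != "none") {
    cat(sprintf("  post hoc: %s (m = %d)\n", object@posthocMethod,
                object@mPosthoc))
    print(object@posthoc, digits = 4)
  }
})

## CorrelationMatrixResult ----------------------------------------------------

setMethod("show", "CorrelationMatrixResult", function(object) {
  cat(sprintf(
    "CorrelationMatrixResult: %d properties, %d significant pairs (alpha %.2g, %d bootstrap reps)\n",
    length(object@vars), sum(object@significant[upper.tri(object@significant)],
                             na.rm = TRUE),
    object@alpha, object@nBoot))
})
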