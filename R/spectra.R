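## The spectral processing chain.
##
## Input spectra are assumed already normalised with respect to the laser
## emission spectrum; the chain implemented here is: division by the average
## epoxy spectrum of the measurement session, then min-max rescaling to 0-1
## over the 1600-1800 cm^-1 window, then band quantification.

.sameGrid <- function(a, b) {
  length(a) == length(b) && max(abs(a - b)) <= 1e-9 * mean(abs(a))
}

.windowIdx <- function(grid, window) {
  if (window[1] < min(grid) - 1e-9 || window[2] > max(grid) + 1e-9)
    stop(sprintf("window (%g, %g) outside grid range (%g, %g)",
                 window[1], window[2], min(grid), max(grid)))
  which(grid >= window[1] - 1e-9 & grid <= window[2] + 1e-9)
}

#' Average epoxy spectrum of a measurement session
#'
#' Pointwise mean of all background (category \code{"BG"}) spectra of one
#' session, used as the per-session normalisation reference. The PLL channel
#' is averaged alongside when present in all epoxy spectra.
#'
#' @param spectra List of [Spectrum-class] objects.
#' @param sessionId Session to average; when NULL all spectra are assumed to
#'   share one session.
#' @return A [Spectrum-class] of category \code{"BG"}.
#' @export
averageSessionEpoxy <- function(spectra, sessionId = NULL) {
  if (is(spectra, "Spectrum")) spectra <- list(spectra)
  keep <- vapply(spectra, function(s)
    category(s) == "BG" &&
      (is.null(sessionId) || sessionId(s) == sessionId), logical(1))
  bg <- spectra[keep]
  if (!length(bg))
    stop("no epoxy (BG) spectra in session '",
         if (is.null(sessionId)) "<any>" else sessionId, "'")
  g <- wavenumber(bg[[1]])
  for (s in bg) if (!.sameGrid(g, wavenumber(s))) stop("mixed grids")
  ampM <- vapply(bg, irAmplitude, numeric(length(g)))
  amp <- rowMeans(ampM)
  hasPll <- all(vapply(bg, function(s) length(s@pllFrequency) > 0, logical(1)))
  pll <- if (hasPll)
    rowMeans(vapply(bg, function(s) s@pllFrequency, numeric(length(g))))
  else numeric()
  valid <- Reduce("&", lapply(bg, validMask))
  Spectrum(g, amp, pll, valid = valid, sampleId = sampleId(bg[[1]]),
           sessionId = sessionId(bg[[1]]), category = "BG")
}

#' Normalise a spectrum by the session epoxy reference
#'
#' Pointwise division of the IR amplitude by the average epoxy spectrum of
#' the same session. Points where the epoxy amplitude is zero or negative
#' cannot be normalised and are masked (a warning reports how many).
#' Metadata and the PLL channel are preserved unchanged.
#'
#' @param s A [Spectrum-class].
#' @param epoxyMean The session epoxy reference (see [averageSessionEpoxy()]).
#' @return The normalised [Spectrum-class].
#' @export
epoxyNormalize <- function(s, epoxyMean) {
  if (!.sameGrid(wavenumber(s), wavenumber(epoxyMean)))
    stop("grid mismatch between spectrum and epoxy reference")
  ref <- irAmplitude(epoxyMean)
  bad <- !(ref > 0) | !validMask(epoxyMean)
  out <- irAmplitude(s) / ifelse(bad, NA_real_, ref)
  valid <- validMask(s) & !bad
  nMasked <- sum(!valid & validMask(s))
  if (nMasked > 0)
    warning(nMasked, " point(s) masked: non-positive epoxy reference")
  Spectrum(wavenumber(s), out, s@pllFrequency, valid = valid,
           sampleId = sampleId(s), sessionId = sessionId(s),
           category = category(s), position = s@position)
}

#' Min-max rescale a spectrum over a window
#'
#' Affinely rescales the whole spectrum so that its minimum over the window
#' is 0 and its maximum is 1 (window endpoints inclusive). Values outside
#' the window may leave the unit interval. A spectrum that is constant
#' within the window is degenerate and raises an error.
#'
#' @param s A [Spectrum-class].
#' @param window Numeric (lo, hi) wavenumber window in cm^-1.
#' @return The rescaled [Spectrum-class].
#' @export
minmaxNormalize <- function(s, window = c(1600, 1800)) {
  g <- wavenumber(s)
  idx <- .windowIdx(g, window)
  idx <- idx[validMask(s)[idx]]
  if (!length(idx)) stop("no valid points in window")
  vals <- irAmplitude(s)[idx]
  lo <- min(vals); hi <- max(vals)
  if (hi - lo <= 0)
    stop("degenerate spectrum: constant within the normalisation window")
  Spectrum(g, (irAmplitude(s) - lo) / (hi - lo), s@pllFrequency,
           valid = validMask(s), sampleId = sampleId(s),
           sessionId = sessionId(s), category = category(s),
           position = s@position)
}

#' Integrated beta-sheet content of a processed spectrum
#'
#' Trapezoidal integral of the IR amplitude over the beta-sheet band
#' (default 1615-1635 cm^-1). Band endpoints falling between grid points are
#' handled by integrating the piecewise-linear interpolant exactly, so a
#' unit-amplitude spectrum integrates to the band width.
#'
#' @param s A processed [Spectrum-class] (epoxy-normalised and min-max
#'   rescaled).
#' @param band Numeric (lo, hi) in cm^-1.
#' @return Integral in a.u. * cm^-1.
#' @examples
#' s <- Spectrum(wavenumberGrid(), rep(1, 501), category = "IB")
#' betaSheetContent(s)  # 20
#' @export
betaSheetContent <- function(s, band = c(1615, 1635)) {
  g <- wavenumber(s)
  if (band[1] < min(g) || band[2] > max(g))
    stop("band outside grid")
  amp <- irAmplitude(s)
  xs <- sort(unique(c(band, g[g > band[1] & g < band[2]])))
  ys <- stats::approx(g, amp, xout = xs)$y
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
}

#' Mean band intensity around a centre wavenumber
#'
#' Mean IR amplitude over the inclusive window
#' [center - halfwidth, center + halfwidth]; the mean (rather than the
#' integral) keeps values comparable across window widths.
#'
#' @param s A [Spectrum-class].
#' @param center Band centre in cm^-1 (e.g. 1628 or 1678).
#' @param halfwidth Half window width in cm^-1.
#' @return Mean amplitude (a.u.).
#' @export
bandIntensity <- function(s, center, halfwidth = 5) {
  g <- wavenumber(s)
  idx <- .windowIdx(g, c(center - halfwidth, center + halfwidth))
  idx <- idx[validMask(s)[idx]]
  if (!length(idx)) stop("no valid points in band window")
  mean(irAmplitude(s)[idx])
}

#' Smoothed second-derivative spectrum
#'
#' Savitzky-Golay second derivative (local polynomial fit): absorption bands
#' appear as negative minima, and sub-band shoulders that overlap in the raw
#' amide-I envelope are resolved. Defaults (9-point window, cubic) resolve
#' amide-I sub-bands of 10-20 cm^-1 width on a 2 cm^-1 grid.
#'
#' @param s A [Spectrum-class].
#' @param smoothWindowPoints Odd window length in grid points
#'   (>= polyOrder + 2).
#' @param polyOrder Polynomial order of the local fit.
#' @return A [Spectrum-class] holding the second derivative
#'   (a.u. per (cm^-1)^2).
#' @export
secondDerivative <- function(s, smoothWindowPoints = 9, polyOrder = 3) {
  if (smoothWindowPoints %% 2 != 1)
    stop("smoothing window must be odd")
  if (smoothWindowPoints < polyOrder + 2)
    stop("smoothing window must be >= polyOrder + 2")
  if (polyOrder < 2)
    stop("polyOrder must be >= 2 for a second derivative")
  g <- wavenumber(s)
  step <- g[2] - g[1]
  d2 <- signal::sgolayfilt(irAmplitude(s), p = polyOrder,
                           n = smoothWindowPoints, m = 2, ts = step)
  Spectrum(g, d2, s@pllFrequency, valid = validMask(s),
           sampleId = sampleId(s), sessionId = sessionId(s),
           category = category(s), position = s@position)
}

#' Reduce a spectrum's PLL channel to a single value
#'
#' Mean PLL frequency over the given window (default 1600-1650 cm^-1) minus
#' the session epoxy PLL reference.
#'
#' @param s A [Spectrum-class] with a PLL channel.
#' @param window Numeric (lo, hi) in cm^-1.
#' @param sessionEpoxyPll Scalar reference in kHz (see
#'   [sessionEpoxyPllReference()]).
#' @return PLL difference in kHz.
#' @export
pllSummary <- function(s, window = c(1600, 1650), sessionEpoxyPll = 0) {
  if (!length(s@pllFrequency))
    stop("spectrum has no PLL channel")
  idx <- .windowIdx(wavenumber(s), window)
  idx <- idx[validMask(s)[idx]]
  mean(s@pllFrequency[idx]) - sessionEpoxyPll
}

#' @rdname pllSummary
#' @param spectra List of spectra containing the session's BG spectra.
#' @param sessionId Session identifier (NULL = all one session).
#' @export
sessionEpoxyPllReference <- function(spectra, sessionId = NULL,
                                     window = c(1600, 1650)) {
  epoxy <- averageSessionEpoxy(spectra, sessionId)
  if (!length(epoxy@pllFrequency))
    stop("epoxy spectra carry no PLL channel")
  idx <- .windowIdx(wavenumber(epoxy), window)
  mean(epoxy@pllFrequency[idx])
}

#' Run the full spectral processing chain over a collection
#'
#' For each session: average its epoxy spectra, divide every non-background
#' spectrum by that reference, min-max rescale over \code{window}.
#'
#' @param spectra List of [Spectrum-class] objects (all sessions mixed).
#' @param window Min-max normalisation window.
#' @return List of processed spectra (background spectra are dropped).
#' @export
processSpectra <- function(spectra, window = c(1600, 1800)) {
  sessions <- unique(vapply(spectra, sessionId, character(1)))
  out <- list()
  for (ses in sessions) {
    epoxy <- averageSessionEpoxy(spectra, ses)
    inSes <- vapply(spectra, function(s)
      sessionId(s) == ses && category(s) != "BG", logical(1))
    out <- c(out, lapply(spectra[inSes], function(s)
      minmaxNormalize(epoxyNormalize(s, epoxy), window)))
  }
  out
}
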