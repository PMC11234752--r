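## Map-level corrections: drift registration, PLL line flattening, ratio maps.

## FFT cross-correlation over integer lags, restricted to |lag| <= maxShift.
## Returns the lag (dx, dy) maximizing the correlation of ref(p) with
## mov(p + lag), with quadratic subpixel interpolation of the peak.
.bestShift <- function(ref, mov, maxShift) {
  h <- nrow(ref); w <- ncol(ref)
  a <- ref - mean(ref); b <- mov - mean(mov)
  ## circular cross-correlation c(lag) = sum_p a(p) * b(p + lag)
  cc <- Re(stats::fft(stats::fft(b) * Conj(stats::fft(a)), inverse = TRUE)) /
    (h * w)
  lagR <- c(0:(h - 1)); lagR[lagR > h / 2] <- lagR[lagR > h / 2] - h
  lagC <- c(0:(w - 1)); lagC[lagC > w / 2] <- lagC[lagC > w / 2] - w
  keep <- abs(lagR) <= maxShift
  keepC <- abs(lagC) <= maxShift
  sub <- cc[keep, keepC, drop = FALSE]
  idx <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  dy <- lagR[keep][idx[1]]; dx <- lagC[keepC][idx[2]]
  atBound <- max(abs(dx), abs(dy)) >= maxShift
  ## quadratic subpixel refinement from the two circular neighbours
  peak1d <- function(cm1, c0, cp1) {
    den <- cm1 - 2 * c0 + cp1
    if (den >= 0) 0 else 0.5 * (cm1 - cp1) / den
  }
  at <- function(dyy, dxx) cc[(dyy %% h) + 1, (dxx %% w) + 1]
  ddy <- peak1d(at(dy - 1, dx), at(dy, dx), at(dy + 1, dx))
  ddx <- peak1d(at(dy, dx - 1), at(dy, dx), at(dy, dx + 1))
  list(dx = dx + ddx, dy = dy + ddy, atBound = atBound)
}

## NCC objective for a candidate transform
.regScore <- function(ref, mov, M) {
  wp <- .warpBilinear(mov, M)
  .ncc(ref, wp$data)
}

#' Register the 1625 cm^-1 dataset onto the 1650 cm^-1 reference
#'
#' Estimates the inter-map drift transform by maximising the normalized
#' cross-correlation (NCC) of the two Height (trace) maps, in two stages:
#' first a rigid transform (integer-lag FFT cross-correlation with subpixel
#' peak interpolation, combined with a coarse-then-refined rotation search),
#' then an affine refinement of all six parameters initialized at the rigid
#' optimum, with the linear part constrained to within \code{maxScaleDev}
#' (default 5\%) of a rotation to prevent degenerate fits. The final
#' transform is applied to every 1625 channel with bilinear resampling;
#' pixels that sample outside the source frame are masked.
#'
#' @param pair A [DatasetPair-class]; both datasets must contain a Height
#'   trace map.
#' @param maxShiftPx Translation search bound in pixels.
#' @param rotRangeDeg,rotStepDeg Coarse rotation search range and step.
#' @param maxScaleDev Allowed deviation of the singular values of the linear
#'   part from 1 in the affine stage.
#' @param refine Run the local optimisation stages (disable for the pure
#'   FFT translation estimate).
#' @return The pair with \code{transform} set and all 1625 channels
#'   resampled onto the reference frame.
#' @export
registerPair <- function(pair, maxShiftPx = 16, rotRangeDeg = 3,
                         rotStepDeg = 0.5, maxScaleDev = 0.05,
                         refine = TRUE) {
  stopifnot(is(pair, "DatasetPair"))
  ref <- mapData(getChannel(pair@ds1650, "Height", "trace"))
  mov <- mapData(getChannel(pair@ds1625, "Height", "trace"))
  if (stats::sd(ref) == 0 || stats::sd(mov) == 0)
    stop("registration unidentifiable: flat height map")
  h <- nrow(ref); w <- ncol(ref)
  ctr <- c((w - 1) / 2, (h - 1) / 2)

  ## --- stage 1: rigid ------------------------------------------------------
  thetas <- seq(-rotRangeDeg, rotRangeDeg, by = rotStepDeg) * pi / 180
  best <- NULL
  for (th in thetas) {
    movR <- if (th == 0) mov else {
      wp <- .warpBilinear(mov, affineRotation(th, ctr))
      wp$data[!wp$valid] <- mean(mov)
      wp$data
    }
    s <- .bestShift(ref, movR, maxShiftPx)
    M <- affineRotation(th, ctr) %*% affineTranslation(s$dx, s$dy)
    sc <- .regScore(ref, mov, M)
    if (is.null(best) || sc > best$score)
      best <- list(theta = th, dx = s$dx, dy = s$dy, score = sc,
                   atBound = s$atBound)
  }
  if (best$atBound)
    warning("correlation peak at translation search bound")
  if (refine) {
    obj <- function(p) {
      M <- affineRotation(p[1], ctr) %*% affineTranslation(p[2], p[3])
      -.regScore(ref, mov, M)
    }
    op <- stats::optim(c(best$theta, best$dx, best$dy), obj,
                       method = "Nelder-Mead",
                       control = list(maxit = 250, reltol = 1e-10))
    best[c("theta", "dx", "dy")] <- as.list(op$par)
  }
  M1 <- affineRotation(best$theta, ctr) %*%
    affineTranslation(best$dx, best$dy)

  ## --- stage 2: affine refinement ------------------------------------------
  M <- M1
  if (refine) {
    par0 <- c(M1[1, 1], M1[1, 2], M1[2, 1], M1[2, 2], M1[1, 3], M1[2, 3])
    obj2 <- function(p) {
      L <- matrix(p[1:4], 2, 2, byrow = TRUE)
      sv <- svd(L, nu = 0, nv = 0)$d
      pen <- sum(pmax(0, abs(sv - 1) - maxScaleDev))^2 * 1e4
      Mc <- rbind(cbind(L, p[5:6]), c(0, 0, 1))
      -.regScore(ref, mov, Mc) + pen
    }
    op2 <- stats::optim(par0, obj2, method = "Nelder-Mead",
                        control = list(maxit = 600, reltol = 1e-10))
    p <- op2$par
    M <- rbind(matrix(c(p[1:2], p[5], p[3:4], p[6]), 2, 3, byrow = TRUE),
               c(0, 0, 1))
  }

  pair@transform <- M
  pair@ds1625 <- .resampleDataset(pair@ds1625, M)
  validObject(pair)
  pair
}

.resampleDataset <- function(ds, M) {
  ds@channels <- lapply(ds@channels, function(cm) {
    wp <- .warpBilinear(cm@data, M, cm@valid)
    d <- wp$data
    d[!wp$valid] <- 0
    ChannelMap(cm@channel, d, cm@direction, cm@units, valid = wp$valid)
  })
  ds
}

#' Flatten line-by-line PLL frequency drift
#'
#' Computes the average PLL frequency of epoxy pixels for every scan line,
#' smooths this profile with a centered rolling mean, and subtracts the
#' smoothed profile from the whole map. Scan lines without any epoxy pixel
#' get their profile value by linear interpolation from neighbouring lines
#' (and are reported in a message). Edge lines use symmetric, truncated
#' windows so a linear drift ramp is removed exactly over the full map.
#'
#' @param pll A PLLFrequency [ChannelMap-class] (or plain matrix).
#' @param epoxyMask Logical matrix: TRUE for epoxy (background) pixels.
#' @param rollingWindowLines Odd rolling-mean window in scan lines.
#' @return The corrected map, same class as the input.
#' @export
correctPllMap <- function(pll, epoxyMask, rollingWindowLines = 17) {
  isCM <- is(pll, "ChannelMap")
  m <- if (isCM) pll@data else as.matrix(pll)
  v <- if (isCM) pll@valid else is.finite(m)
  epoxyMask <- as.matrix(epoxyMask)
  stopifnot(identical(dim(m), dim(epoxyMask)))
  if (!any(epoxyMask))
    stop("epoxy mask is empty")
  if (rollingWindowLines %% 2L == 0L)
    stop("rolling window must be odd")
  use <- epoxyMask & v
  lineMean <- vapply(seq_len(nrow(m)), function(r) {
    px <- m[r, use[r, ]]
    if (length(px)) mean(px) else NA_real_
  }, numeric(1))
  bad <- which(!is.finite(lineMean))
  if (length(bad)) {
    message(length(bad), " scan line(s) without epoxy pixels; profile interpolated: ",
            paste(utils::head(bad, 10), collapse = ", "),
            if (length(bad) > 10) ", ..." else "")
    good <- which(is.finite(lineMean))
    if (length(good) < 2) stop("too few lines with epoxy pixels")
    lineMean[bad] <- stats::approx(good, lineMean[good], xout = bad,
                                   rule = 2)$y
  }
  prof <- .rollMeanSym(lineMean, rollingWindowLines)
  out <- m - prof   # recycles down columns = per-line subtraction
  if (isCM) ChannelMap(pll@channel, out, pll@direction, pll@units, valid = v)
  else out
}

#' Pixelwise 1625/1650 amplitude ratio map
#'
#' Divides the registered 1625 cm^-1 amplitude map by the 1650 cm^-1 one.
#' Pixels whose 1650 amplitude falls below the given quantile of the epoxy
#' amplitude distribution are masked, guarding against division blow-up in
#' low-signal regions; invalid input pixels propagate.
#'
#' @param amp1625,amp1650 [ChannelMap-class] objects or matrices of equal
#'   shape (1625 already registered onto the 1650 frame).
#' @param minDenominatorQuantile Quantile of the epoxy 1650 amplitude below
#'   which pixels are masked.
#' @param epoxyMask Logical matrix of epoxy pixels for the quantile; the
#'   whole valid map is used when NULL.
#' @return A [ChannelMap-class] with channel \code{"Ratio"}.
#' @export
ratioMap <- function(amp1625, amp1650, minDenominatorQuantile = 0.01,
                     epoxyMask = NULL) {
  num <- if (is(amp1625, "ChannelMap")) amp1625@data else as.matrix(amp1625)
  nv <- if (is(amp1625, "ChannelMap")) amp1625@valid else is.finite(num)
  den <- if (is(amp1650, "ChannelMap")) amp1650@data else as.matrix(amp1650)
  dv <- if (is(amp1650, "ChannelMap")) amp1650@valid else is.finite(den)
  if (!identical(dim(num), dim(den)))
    stop("shape mismatch between 1625 and 1650 maps")
  ref <- if (is.null(epoxyMask)) den[dv] else den[as.matrix(epoxyMask) & dv]
  floorVal <- stats::quantile(ref, minDenominatorQuantile, names = FALSE,
                              na.rm = TRUE)
  ok <- nv & dv & den >= floorVal & den > 0
  out <- matrix(0, nrow(num), ncol(num))
  out[ok] <- num[ok] / den[ok]
  ChannelMap("Ratio", out, "trace", units = "", valid = ok)
}
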