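## Internal numeric helpers shared across modules.

## coerce EBImage results back to a plain matrix
.em <- function(x) {
  if (methods::is(x, "Image")) x <- EBImage::imageData(x)
  d <- dim(x)
  if (length(d) > 2L) x <- array(x, d[1:2])
  as.matrix(x)
}

#' Euclidean disk structuring element
#'
#' Binary disk of the given radius: pixel (dx, dy) belongs to the element iff
#' dx^2 + dy^2 <= r^2. This is also the definition used for disks planted by
#' the phantom generator, so morphological reasoning about minimum detectable
#' object size is exact.
#'
#' @param radiusPx Disk radius in pixels (>= 0).
#' @return A (2r+1) x (2r+1) 0/1 matrix.
#' @examples
#' sum(diskKernel(2))  # 13 pixels
#' @export
diskKernel <- function(radiusPx) {
  r <- radiusPx
  stopifnot(r >= 0)
  off <- seq(-floor(r), floor(r))
  k <- outer(off^2, off^2, "+") <= r^2 + 1e-9
  storage.mode(k) <- "integer"
  k
}

## run expr with a deterministic local RNG state, restoring the caller's
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## centered rolling mean with symmetric, truncated windows at the edges.
## Symmetry makes the smoother exact on linear ramps at every position,
## which matters when the smoothed profile is a drift ramp.
.rollMeanSym <- function(x, window) {
  n <- length(x)
  if (window %% 2L == 0L)
    stop("rolling window must be odd")
  half <- (window - 1L) %/% 2L
  out <- numeric(n)
  cs <- cumsum(c(0, x))
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)
    out[i] <- (cs[i + h + 1L] - cs[i - h]) / (2L * h + 1L)
  }
  out
}

## bilinear resampling of img through a 3x3 pixel-coordinate affine:
## out[r, c] = img(M %*% (c-1, r-1, 1)), NA outside the source frame.
## Coordinates are 0-based with x = column, y = row (origin top-left).
.warpBilinear <- function(img, M, valid = NULL) {
  h <- nrow(img); w <- ncol(img)
  xy <- cbind(rep(seq_len(w) - 1, each = h),   # x per output pixel
              rep(seq_len(h) - 1, times = w),  # y
              1)
  src <- xy %*% t(M)
  x <- src[, 1]; y <- src[, 2]
  inb <- x >= 0 & x <= w - 1 & y >= 0 & y <= h - 1
  x0 <- floor(x); y0 <- floor(y)
  ## clamp so the upper edge stays interpolable
  x0 <- pmin(pmax(x0, 0), w - 2); y0 <- pmin(pmax(y0, 0), h - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- (x0) * h + y0 + 1        # column-major linear index of (y0, x0)
  v00 <- img[i00];         v10 <- img[i00 + h]
  v01 <- img[i00 + 1];     v11 <- img[i00 + h + 1]
  out <- (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
         (1 - fx) * fy * v01 + fx * fy * v11
  out[!inb] <- NA_real_
  outMask <- inb
  if (!is.null(valid)) {
    m00 <- valid[i00]; m10 <- valid[i00 + h]
    m01 <- valid[i00 + 1]; m11 <- valid[i00 + h + 1]
    outMask <- inb & m00 & m10 & m01 & m11
    out[!outMask] <- NA_real_
  }
  list(data = matrix(out, h, w), valid = matrix(outMask, h, w))
}

## normalized cross-correlation over jointly finite pixels
.ncc <- function(a, b) {
  v <- is.finite(a) & is.finite(b)
  if (sum(v) < 64) return(-Inf)
  a <- a[v]; b <- b[v]
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(-Inf)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

.dfNum <- function(x) vapply(x, is.numeric, logical(1))
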