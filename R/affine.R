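## 2D affine transforms in pixel coordinates.
##
## Convention: 3x3 homogeneous matrices acting on 0-based pixel coordinates
## (x = column, y = row, origin at the top-left corner). A pair transform M
## maps reference-frame coordinates to moving-frame coordinates, so
## resampling the moving image at M %*% p aligns it with the reference.

#' Build elementary affine transforms
#'
#' Helpers constructing 3x3 pixel-coordinate affine matrices: a translation,
#' a rotation about an arbitrary centre, and a scan shear (x displaced
#' proportionally to y, the slow scan axis, as produced by nonconstant stage
#' drift).
#'
#' @param dx,dy Translation in pixels.
#' @param thetaRad Rotation angle in radians (about \code{center}).
#' @param center Numeric (x, y) centre of rotation in pixel coordinates.
#' @param shear Shear fraction: x' = x + shear * y.
#' @return A 3x3 numeric matrix with last row (0, 0, 1).
#' @examples
#' affineTranslation(5, -3)
#' @export
affineTranslation <- function(dx, dy) {
  matrix(c(1, 0, dx,
           0, 1, dy,
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' @rdname affineTranslation
#' @export
affineRotation <- function(thetaRad, center = c(0, 0)) {
  R <- matrix(c(cos(thetaRad), -sin(thetaRad), 0,
                sin(thetaRad),  cos(thetaRad), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  affineTranslation(center[1], center[2]) %*% R %*%
    affineTranslation(-center[1], -center[2])
}

#' @rdname affineTranslation
#' @export
affineShear <- function(shear) {
  matrix(c(1, shear, 0,
           0, 1, 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' Apply an affine transform to points
#'
#' @param M 3x3 affine matrix.
#' @param xy n x 2 matrix (or length-2 vector) of (x, y) pixel coordinates.
#' @return n x 2 matrix of transformed coordinates.
#' @export
applyAffine <- function(M, xy) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  out <- cbind(xy, 1) %*% t(M)
  out[, 1:2, drop = FALSE]
}
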