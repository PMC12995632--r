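# Rigid in-plane transforms.
#
# Coordinate convention (used package-wide): pixels are indexed (row, col) =
# (y, x), 0-based, with pixel centers at integer coordinates. Rotations are
# about the geometric image center ((H-1)/2, (W-1)/2), measured in degrees,
# positive in the direction from the +x axis toward the +y axis (image rows
# grow downward). A transform acts on a point p = (y, x) as
#   p' = R(theta) %*% (p - c) + c + (dy, dx).

#' Create a rigid in-plane transform
#'
#' @param theta_deg Rotation angle in degrees about the image center.
#' @param dx_px,dy_px Translation in pixels along columns (x) and rows (y).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(theta_deg = 0, dx_px = 0, dy_px = 0) {
  stopifnot(is.finite(theta_deg), is.finite(dx_px), is.finite(dy_px))
  structure(
    list(theta_deg = as.numeric(theta_deg),
         dx_px = as.numeric(dx_px),
         dy_px = as.numeric(dy_px)),
    class = "rigid_transform"
  )
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> theta = %.4f deg, dx = %.4f px, dy = %.4f px\n",
              x$theta_deg, x$dx_px, x$dy_px))
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param transform A `rigid_transform`.
#' @param y,x Numeric vectors of point coordinates (0-based pixel units).
#' @param dim Image dimensions `c(nrow, ncol)` defining the rotation center.
#' @return A list with components `y` and `x`.
#' @export
apply_rigid <- function(transform, y, x, dim) {
  stopifnot(inherits(transform, "rigid_transform"), length(dim) == 2)
  cy <- (dim[1] - 1) / 2
  cx <- (dim[2] - 1) / 2
  a <- transform$theta_deg * pi / 180
  xr <- cos(a) * (x - cx) - sin(a) * (y - cy)
  yr <- sin(a) * (x - cx) + cos(a) * (y - cy)
  list(y = yr + cy + transform$dy_px, x = xr + cx + transform$dx_px)
}

#' Compose two rigid transforms
#'
#' `compose_rigid(t2, t1)` returns the transform equivalent to applying `t1`
#' first, then `t2`.
#'
#' @param t2,t1 `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_rigid <- function(t2, t1) {
  a <- t2$theta_deg * pi / 180
  # translation vector of t1 rotated by t2's rotation
  dx <- cos(a) * t1$dx_px - sin(a) * t1$dy_px + t2$dx_px
  dy <- sin(a) * t1$dx_px + cos(a) * t1$dy_px + t2$dy_px
  rigid_transform(t1$theta_deg + t2$theta_deg, dx, dy)
}

#' Invert a rigid transform
#'
#' @param transform A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_rigid <- function(transform) {
  a <- -transform$theta_deg * pi / 180
  dx <- -(cos(a) * transform$dx_px - sin(a) * transform$dy_px)
  dy <- -(sin(a) * transform$dx_px + cos(a) * transform$dy_px)
  rigid_transform(-transform$theta_deg, dx, dy)
}

#' Warp an image by a rigid transform
#'
#' Resamples `image` so that the output is `image` moved by `transform`
#' (forward semantics; internally a backward warp through the inverse).
#' Out-of-frame samples are filled with 0.
#'
#' @param image Numeric matrix.
#' @param transform A `rigid_transform`.
#' @param interp `"bilinear"` (default, for intensity images) or `"nearest"`
#'   (for label/binary masks).
#' @return Numeric matrix of the same dimensions.
#' @export
warp_rigid <- function(image, transform, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  stopifnot(is.matrix(image))
  h <- nrow(image); w <- ncol(image)
  inv <- invert_rigid(transform)
  # output pixel grid (0-based)
  yy <- rep(0:(h - 1), times = w)
  xx <- rep(0:(w - 1), each = h)
  src <- apply_rigid(inv, yy, xx, dim = c(h, w))
  sy <- src$y; sx <- src$x
  out <- numeric(h * w)
  if (interp == "nearest") {
    iy <- round(sy); ix <- round(sx)
    ok <- iy >= 0 & iy <= h - 1 & ix >= 0 & ix <= w - 1
    out[ok] <- image[cbind(iy[ok] + 1, ix[ok] + 1)]
  } else {
    y0 <- floor(sy); x0 <- floor(sx)
    fy <- sy - y0;   fx <- sx - x0
    ok <- y0 >= 0 & y0 <= h - 2 & x0 >= 0 & x0 <= w - 2
    # exact grid points on the last row/col are still valid
    edge <- (y0 == h - 1 & fy < 1e-9 & x0 >= 0 & x0 <= w - 1) |
      (x0 == w - 1 & fx < 1e-9 & y0 >= 0 & y0 <= h - 1)
    ok2 <- ok | (edge & y0 >= 0 & x0 >= 0 & y0 <= h - 1 & x0 <= w - 1)
    y0c <- pmin(y0, h - 2); x0c <- pmin(x0, w - 2)
    i <- which(ok2)
    if (length(i)) {
      y0i <- y0c[i]; x0i <- x0c[i]
      fyi <- sy[i] - y0i; fxi <- sx[i] - x0i
      v00 <- image[cbind(y0i + 1, x0i + 1)]
      v10 <- image[cbind(y0i + 2, x0i + 1)]
      v01 <- image[cbind(y0i + 1, x0i + 2)]
      v11 <- image[cbind(y0i + 2, x0i + 2)]
      out[i] <- v00 * (1 - fyi) * (1 - fxi) + v10 * fyi * (1 - fxi) +
        v01 * (1 - fyi) * fxi + v11 * fyi * fxi
    }
  }
  matrix(out, h, w)
}

# validity mask of a warp: TRUE where the backward sample fell inside the frame
warp_valid_mask <- function(dim, transform) {
  h <- dim[1]; w <- dim[2]
  inv <- invert_rigid(transform)
  yy <- rep(0:(h - 1), times = w)
  xx <- rep(0:(w - 1), each = h)
  src <- apply_rigid(inv, yy, xx, dim = c(h, w))
  matrix(src$y >= 0 & src$y <= h - 1 & src$x >= 0 & src$x <= w - 1, h, w)
}
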