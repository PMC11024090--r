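# Projective-geometry primitives: 4-point homography fitting, point and image
# warping, destination-corner construction, Theil-Sen regression, and
# inscribed-rectangle cropping.

#' Construct a line from slope and intercept
#' @param slope dy/dx in pixel coordinates (y increases downward).
#' @param intercept y at x = 0, in pixels.
#' @return An object of class `rw_line`.
#' @export
rw_line <- function(slope, intercept) {
  stopifnot(is.finite(slope), is.finite(intercept))
  structure(list(slope = slope, intercept = intercept), class = "rw_line")
}

#' @export
print.rw_line <- function(x, ...) {
  cat(sprintf("line: y = %.5g x + %.5g\n", x$slope, x$intercept))
  invisible(x)
}

line_y <- function(line, x) line$slope * x + line$intercept

#' Construct a quadrilateral from four corners
#'
#' Corners are ordered clockwise from the top-left. Each corner is a length-2
#' numeric `(x, y)`.
#' @param tl,tr,br,bl Corner coordinates.
#' @return A 4 x 2 matrix with rows tl, tr, br, bl.
#' @export
quad <- function(tl, tr, br, bl) {
  q <- rbind(tl = tl, tr = tr, br = br, bl = bl)
  colnames(q) <- c("x", "y")
  q
}

quad_area <- function(q) {
  x <- q[, 1]; y <- q[, 2]
  abs(sum(x * y[c(2:4, 1)] - x[c(2:4, 1)] * y)) / 2
}

#' Fit the homography mapping one quadrilateral onto another
#'
#' Solves the four corner correspondences as an 8-unknown linear system with
#' the matrix element `h[3,3]` fixed to 1, the standard parameterization for
#' a perspective transformation between two views of a plane.
#'
#' @param src,dst 4 x 2 corner matrices (see [quad()]), in matching order.
#' @return A 3 x 3 homography matrix with `H[3,3] = 1`.
#' @export
fit_homography <- function(src, dst) {
  stopifnot(nrow(src) == 4, nrow(dst) == 4)
  if (quad_area(src) < 1e-9 || quad_area(dst) < 1e-9)
    stop("degenerate quadrilateral: zero area")
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; xp <- dst[i, 1]; yp <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -xp * x, -xp * y)
    A[2 * i, ] <- c(0, 0, 0, x, y, 1, -yp * x, -yp * y)
    b[2 * i - 1] <- xp; b[2 * i] <- yp
  }
  h <- tryCatch(solve(A, b), error = function(e)
    stop("singular configuration: three collinear corners or degenerate quad"))
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

#' Apply a homography to points
#'
#' Multiplies homogeneous coordinates by `H` and divides by the per-point
#' scaling factor (the third homogeneous component).
#'
#' @param H 3 x 3 homography matrix.
#' @param pts An n x 2 matrix of `(x, y)` points (or a length-2 vector).
#' @return An n x 2 matrix of mapped points.
#' @export
apply_homography <- function(H, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, 1)
  P <- H %*% rbind(t(pts), 1)
  lambda <- P[3, ]
  if (any(abs(lambda) < 1e-12)) stop("point maps to infinity (zero scaling factor)")
  out <- cbind(x = P[1, ] / lambda, y = P[2, ] / lambda)
  out
}

#' Warp an image by a homography
#'
#' Each destination pixel is sampled at its inverse-mapped source location by
#' bilinear interpolation; destinations with no source sample are black.
#'
#' @param img Numeric raster.
#' @param H 3 x 3 homography mapping source to destination coordinates.
#' @param out_size `c(width, height)` of the output canvas.
#' @param fill Fill intensity outside the mapped region.
#' @return A raster of the requested size.
#' @export
warp_image <- function(img, H, out_size, fill = 0) {
  Hinv <- tryCatch(solve(H), error = function(e) stop("homography not invertible"))
  res <- warp_homography_cpp(as.numeric(img), dim(img), Hinv,
                             as.integer(out_size[1]), as.integer(out_size[2]), fill)
  res$img
}

#' Destination corners for a given compression factor
#'
#' For a source plane of width `w` and height `h`, the two destination corners
#' closest to the camera are placed symmetrically about the vertical midline
#' at the bottom of the canvas, separated by `d = x_cf * w`.
#'
#' @param w,h Source-plane width and height in pixels.
#' @param x_cf Compression factor in `(0, 1]`.
#' @return A list with `C_L` and `C_R`, each `(x, y)`.
#' @export
destination_corners <- function(w, h, x_cf) {
  stopifnot(w > 0, h > 0)
  if (!is.finite(x_cf) || x_cf <= 0 || x_cf > 1)
    stop("compression factor must lie in (0, 1]")
  d <- x_cf * w
  list(C_L = c(x = w / 2 - d / 2, y = h), C_R = c(x = w / 2 + d / 2, y = h))
}

#' Theil-Sen robust line fit
#'
#' Slope is the median over all unique pairwise slopes (pairs with equal x
#' excluded); the intercept is the median of the per-point residual
#' intercepts `y_i - slope * x_i`. No hyperparameters.
#'
#' @param x,y Point coordinates, or `x` an n x 2 matrix.
#' @return An [rw_line()].
#' @export
theil_sen_fit <- function(x, y = NULL) {
  if (is.null(y)) { y <- x[, 2]; x <- x[, 1] }
  n <- length(x)
  stopifnot(n >= 2)
  dx <- outer(x, x, "-"); dy <- outer(y, y, "-")
  keep <- upper.tri(dx) & dx != 0
  if (!any(keep)) stop("all x identical: vertical data cannot be fit as y = mx + b")
  slope <- median(dy[keep] / dx[keep])
  rw_line(slope, median(y - slope * x))
}

#' Largest axis-aligned rectangle inscribed in a rotated image
#'
#' Closed-form solution for the maximal-area axis-aligned rectangle contained
#' in a `w x h` rectangle rotated by `theta` degrees about its centre. The
#' returned rectangle is centred on the image centre.
#'
#' @param w,h Image width and height in pixels.
#' @param theta Rotation angle in degrees, `|theta| < 90`.
#' @return A list with `width`, `height`, and the crop offsets `x0`, `y0`
#'   (distance from the original top-left corner to the crop's top-left).
#' @export
largest_inscribed_rect_after_rotation <- function(w, h, theta) {
  stopifnot(abs(theta) < 90)
  a <- abs(theta) * pi / 180
  s <- sin(a); c <- cos(a)
  if (s < 1e-12) return(list(width = w, height = h, x0 = 0, y0 = 0))
  side_long <- max(w, h); side_short <- min(w, h)
  if (side_short <= 2 * s * c * side_long || abs(s - c) < 1e-10) {
    # half-constrained: two crop corners touch the longer rotated sides
    x <- 0.5 * side_short
    if (w >= h) { wr <- x / s; hr <- x / c } else { wr <- x / c; hr <- x / s }
  } else {
    cos2a <- c * c - s * s
    wr <- (w * c - h * s) / cos2a
    hr <- (h * c - w * s) / cos2a
  }
  list(width = wr, height = hr, x0 = (w - wr) / 2, y0 = (h - hr) / 2)
}

#' Largest axis-aligned rectangle of valid pixels in a mask
#'
#' @param valid Binary matrix; 1 marks usable pixels.
#' @return A list with 1-based inclusive bounds `r1, c1, r2, c2` and `area`.
#' @export
largest_rect_in_mask <- function(valid) {
  m <- matrix(as.integer(valid != 0), nrow(valid), ncol(valid))
  if (!any(m == 1L)) stop("mask has no valid pixels")
  v <- largest_rect_cpp(m)
  list(r1 = v[1], c1 = v[2], r2 = v[3], c2 = v[4], area = attr(v, "area"))
}

# Rotation homography about a centre point; angle in radians. Rotating points
# by `ang` with tan(ang) = slope maps the direction (1, slope) onto (., 0),
# i.e. levels a line of that slope.
rotation_about <- function(ang, cx, cy) {
  cs <- cos(ang); sn <- sin(ang)
  A <- matrix(c(cs, -sn, sn, cs), 2, 2) # rows: [cs, sn], [-sn, cs]
  t0 <- c(cx, cy) - A %*% c(cx, cy)
  rbind(cbind(A, t0), c(0, 0, 1))
}
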