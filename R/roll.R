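# Camera-roll removal: rotate about the image centre so the horizon becomes
# horizontal, crop away the rotation margins, and carry the horizon intercept
# through the same transformation.

#' Remove camera roll
#'
#' Rotates the image about its centre by the negative arctangent of the
#' horizon slope, crops to the largest inscribed axis-aligned rectangle, and
#' recomputes the horizon as a zero-slope line whose intercept is obtained by
#' transforming the horizon point at the centre column through the same
#' rotation and crop.
#'
#' @param img Raster.
#' @param horizon Result of [detect_horizon()], or a list with field `line`.
#' @return A list with `img` (rotated and cropped raster), `horizon`
#'   (zero-slope line), `rotation` (the 3 x 3 point map used), and `crop`
#'   (`x0`, `y0` offsets removed from the rotated frame).
#' @export
remove_roll <- function(img, horizon) {
  line <- horizon$line
  stopifnot(abs(line$slope) < 1)
  H <- nrow(img); W <- ncol(img)
  ang <- atan(line$slope)
  if (abs(ang) < 1e-12) {
    return(list(img = img, horizon = rw_line(0, line$intercept),
                rotation = diag(3), crop = list(x0 = 0L, y0 = 0L)))
  }
  R <- rotation_about(ang, W / 2, H / 2)
  rot <- warp_image(img, R, c(W, H))
  cr <- largest_inscribed_rect_after_rotation(W, H, ang * 180 / pi)
  r1 <- max(1L, as.integer(ceiling(cr$y0 + 1e-9)) + 1L)
  c1 <- max(1L, as.integer(ceiling(cr$x0 + 1e-9)) + 1L)
  r2 <- min(H, as.integer(floor(cr$y0 + cr$height)))
  c2 <- min(W, as.integer(floor(cr$x0 + cr$width)))
  out <- if (is.matrix(rot)) rot[r1:r2, c1:c2] else rot[r1:r2, c1:c2, , drop = FALSE]
  p <- apply_homography(R, c(W / 2, line_y(line, W / 2)))
  new_int <- p[1, 2] - (r1 - 1L)
  list(img = out, horizon = rw_line(0, new_int),
       rotation = R, crop = list(x0 = c1 - 1L, y0 = r1 - 1L))
}
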