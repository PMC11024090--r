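# Edge-map construction. Two modes are used downstream: "adaptive" (adaptive
# mean thresholding before Canny, which recovers faint edges near the dim
# horizon) for horizon detection, and "standard" (no adaptive step) for
# source-plane and vanishing-line detection.

sobel_gradients <- function(m) {
  # 3x3 Sobel, replicate boundary. gx responds to horizontal intensity change.
  sx <- shift_mat(m, 0, 1) - shift_mat(m, 0, -1)
  gx <- shift_mat(sx, -1, 0) + 2 * sx + shift_mat(sx, 1, 0)
  sy <- shift_mat(m, 1, 0) - shift_mat(m, -1, 0)
  gy <- shift_mat(sy, 0, -1) + 2 * sy + shift_mat(sy, 0, 1)
  list(gx = gx, gy = gy)
}

# Canny edge detector: Sobel gradients, 4-sector non-maximum suppression,
# double threshold, hysteresis. Thresholds are on the L2 gradient magnitude
# of the 8-bit-scaled image.
canny <- function(m, low = 50, high = 150) {
  g <- sobel_gradients(m * 255)
  mag <- sqrt(g$gx^2 + g$gy^2)
  ang <- atan2(g$gy, g$gx) %% pi
  sector <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L
  H <- nrow(m); W <- ncol(m)
  n1 <- matrix(0, H, W); n2 <- matrix(0, H, W)
  offs <- list(`0` = c(0L, 1L), `1` = c(1L, 1L), `2` = c(1L, 0L), `3` = c(1L, -1L))
  for (s in 0:3) {
    idx <- sector == s
    o <- offs[[s + 1L]]
    a <- shift_mat(mag, o[1], o[2]); b <- shift_mat(mag, -o[1], -o[2])
    n1[idx] <- a[idx]; n2[idx] <- b[idx]
  }
  keep <- mag >= n1 & mag >= n2
  strong <- matrix(as.integer(keep & mag >= high), H, W)
  weak <- matrix(as.integer(keep & mag >= low), H, W)
  hysteresis_cpp(strong, weak)
}

# Adaptive mean threshold: foreground where pixel >= local block mean - offset.
adaptive_mean_threshold <- function(m, block = 51L, offset = 0) {
  r <- (block - 1L) %/% 2L
  mu <- box_sum(m, r) / box_count(nrow(m), ncol(m), r)
  (m >= mu - offset) * 1
}

#' Build an edge map
#'
#' Pipeline: grayscale, Gaussian blur, optional adaptive mean thresholding,
#' Canny edge detection. The adaptive step recovers faint edges near the
#' horizon that a global gradient threshold would miss.
#'
#' @param img Raster (grayscale or RGB).
#' @param mode `"adaptive"` or `"standard"`.
#' @param config Tunables; see [rw_config()] (`blur_size`, `blur_sigma`,
#'   `canny_low`, `canny_high`, `adaptive_block`, `adaptive_offset`).
#' @return Binary edge matrix (1 = edge pixel) with attribute `mode`.
#' @export
build_edge_map <- function(img, mode = c("adaptive", "standard"), config = rw_config()) {
  mode <- match.arg(mode)
  g <- gaussian_blur(to_gray(img), config$blur_size, config$blur_sigma)
  if (mode == "adaptive") g <- adaptive_mean_threshold(g, config$adaptive_block, config$adaptive_offset)
  e <- canny(g, config$canny_low, config$canny_high)
  attr(e, "mode") <- mode
  e
}
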