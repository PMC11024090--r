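# Horizon detection. The reef texture produces dense edges while the water
# column produces none, so the horizon is the demarcation in local edge
# density. Bright clutter above the water line (surface, fish) is first made
# invisible by fitting a "water-column line" through randomly sampled
# zero-density pixels and zeroing everything above it; Otsu binarization then
# splits reef from water, and the longest reef contour is regressed.

#' Local edge-density map
#'
#' Per-pixel count of edge pixels within a `(2r+1)^2` window, divided by the
#' global maximum count. An all-zero edge map stays all-zero.
#'
#' @param edges Binary edge matrix.
#' @param radius Window radius in pixels (>= 1).
#' @return Matrix in `[0, 1]`.
#' @export
edge_density_map <- function(edges, radius) {
  stopifnot(radius >= 1)
  r <- as.integer(radius)
  # rate per window area, so truncated border windows are not biased low
  rate <- box_sum(edges, r) / box_count(nrow(edges), ncol(edges), r)
  mx <- max(rate)
  if (mx == 0) return(rate)
  rate / mx
}

density_radius <- function(dim_hw, config) {
  max(config$density_radius_min, round(config$density_radius_frac * sqrt(sum(dim_hw^2))))
}

#' Fit the water-column line
#'
#' Samples `n_samples` zero-density pixels uniformly at random (seeded) and
#' fits a Theil-Sen line through them. Shadow pixels in the reef that also
#' have zero density enter the sample as outliers; the median-based fit is
#' insensitive to them.
#'
#' @param density Edge-density matrix in `[0, 1]`.
#' @param n_samples Number of pixels to sample.
#' @param seed Integer seed for the sampling.
#' @return An [rw_line()].
#' @export
fit_water_column_line <- function(density, n_samples = 100L, seed = 0L) {
  zero_idx <- which(density == 0)
  if (length(zero_idx) < n_samples)
    stop_rw("NO_WATER_COLUMN", "horizon",
            sprintf("only %d zero-density pixels (< %d): no water column visible",
                    length(zero_idx), n_samples))
  sel <- withr::with_seed(seed, sample(zero_idx, n_samples))
  r <- (sel - 1L) %% nrow(density) + 1L
  c <- (sel - 1L) %/% nrow(density) + 1L
  theil_sen_fit(as.numeric(c), as.numeric(r))
}

#' Zero all density above a line
#'
#' Pixels with `y < line(x)` (above the line, y-down convention) are set to
#' zero; all others are unchanged.
#'
#' @param density Edge-density matrix.
#' @param line An [rw_line()].
#' @return Matrix of the same shape.
#' @export
suppress_above_line <- function(density, line) {
  H <- nrow(density); W <- ncol(density)
  ylim <- line_y(line, seq_len(W))
  above <- outer(seq_len(H), ylim, "<")
  density[above] <- 0
  density
}

#' Otsu binarization of a density map
#'
#' The threshold is chosen by exhaustive minimization of the intra-class
#' variance over 256 quantized levels. Output 1 marks the high-density (reef)
#' class. A single-valued map yields an all-zero output.
#'
#' @param density Matrix in `[0, 1]`.
#' @return Binary matrix.
#' @export
otsu_binarize <- function(density) {
  lev <- pmin(as.integer(density * 255), 255L)
  h <- as.numeric(tabulate(lev + 1L, nbins = 256L))  # double: counts overflow int products
  n <- sum(h)
  if (sum(h > 0) < 2) return(matrix(0L, nrow(density), ncol(density)))
  # between-class variance, maximized == intra-class variance minimized
  p <- h / n
  w0 <- cumsum(p)[1:255]
  mu <- cumsum(p * (0:255))[1:255]
  muT <- sum(p * (0:255))
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, 255)
  bcv[valid] <- (muT * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  # plateau of equally optimal splits: take its midpoint
  opt <- which(bcv >= max(bcv) - 1e-12)
  t <- as.integer(round(mean(range(opt)))) - 1L  # class0 = levels <= t
  out <- matrix(as.integer(lev > t), nrow(density), ncol(density))
  attr(out, "threshold") <- (t + 0.5) / 255
  out
}

#' Extract horizon candidate points from a binarized density map
#'
#' Traces the boundary contours of the reef class, keeps the longest, removes
#' points on the image border, and applies a single-pass z-score filter on
#' the y-coordinate to drop shadow-induced excursions.
#'
#' @param binary Binary matrix (1 = reef class).
#' @param zscore z-score cut on y.
#' @return An n x 2 matrix of `(x, y)` points.
#' @export
extract_horizon_points <- function(binary, zscore = 2.5) {
  if (!any(binary == 1)) stop_rw("NO_HORIZON", "horizon", "empty reef class: no contours")
  # external boundaries only: interior holes do not belong to the horizon
  lab <- EBImage::bwlabel(EBImage::fillHull(binary))
  cont <- EBImage::ocontour(lab)
  cont <- cont[[which.max(vapply(cont, nrow, 1L))]]
  # ocontour coords are 0-based (row, col)
  y <- cont[, 1] + 1; x <- cont[, 2] + 1
  H <- nrow(binary); W <- ncol(binary)
  keep <- x > 1 & x < W & y > 1 & y < H
  x <- x[keep]; y <- y[keep]
  if (length(y) < 2) stop_rw("NO_HORIZON", "horizon", "contour entirely on image border")
  s <- sd(y)
  if (is.finite(s) && s > 0) {
    keep <- abs(y - mean(y)) / s <= zscore
    x <- x[keep]; y <- y[keep]
  }
  cbind(x = x, y = y)
}

#' Detect the horizon line of a reefscape image
#'
#' Composition of the edge-density pipeline: adaptive edge map, local edge
#' density, water-column-line suppression, Otsu binarization, longest-contour
#' extraction, and a final Theil-Sen fit. The horizon must intersect the left
#' image edge; a fit that misses it is rejected.
#'
#' @param img Raster (assumed already undistorted).
#' @param config Pipeline configuration, see [rw_config()].
#' @return A list with `line` ([rw_line()]) and `source_mode = "detected"`.
#' @export
detect_horizon <- function(img, config = rw_config()) {
  H <- nrow(img); W <- ncol(img)
  edges <- build_edge_map(img, "adaptive", config)
  density <- edge_density_map(edges, density_radius(c(H, W), config))
  wline <- fit_water_column_line(density, config$n_water_samples, config$seed)
  density <- suppress_above_line(density, wline)
  binary <- otsu_binarize(density)
  pts <- extract_horizon_points(binary, config$zscore_threshold)
  line <- theil_sen_fit(pts)
  if (abs(line$slope) >= 1 || line$intercept < -0.5 * H || line$intercept > 1.5 * H)
    stop_rw("NO_HORIZON", "horizon",
            sprintf("implausible horizon fit (slope %.3f, intercept %.1f)",
                    line$slope, line$intercept))
  if (line$intercept < 0 || line$intercept > H)
    stop_rw("HORIZON_OFF_LEFT_EDGE", "horizon",
            "horizon does not intersect the left image edge")
  list(line = line, source_mode = "detected")
}
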