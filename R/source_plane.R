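# Source-plane detection. Near the horizon, perspective foreshortening makes
# edge orientations collapse toward horizontal (high anisotropy); closer to
# the camera, edges are oriented uniformly (low anisotropy). The "anisotropy
# index" is the row where anisotropy first drops steeply — the top of the
# reliably transformable reef plane.

#' Anisotropy of a set of edge orientations
#'
#' The reciprocal of the variance of arctangent-mapped edge gradients. A
#' degenerate sample (variance below 1e-6) returns `cap`.
#'
#' @param orientations Angles in radians in `(-pi/2, pi/2]`.
#' @param cap Value returned when the variance vanishes.
#' @return A scalar.
#' @export
anisotropy <- function(orientations, cap = 1e6) {
  n <- length(orientations)
  if (n < 2) stop_rw("INSUFFICIENT_EDGES", "source_plane", "need >= 2 orientation samples")
  v <- sum((orientations - mean(orientations))^2) / n
  if (v < 1e-6) return(cap)
  1 / v
}

# Edge-tangent orientation at each pixel: arctan of the Sobel gradient ratio
# gx/gy, mapped to (-pi/2, pi/2]. A horizontal edge (vertical gradient) has
# orientation 0; a vertical edge has pi/2.
edge_orientations <- function(gray) {
  g <- sobel_gradients(gray)
  phi <- atan2(g$gx, g$gy)  # ratio convention: tangent angle
  phi[phi > pi / 2] <- phi[phi > pi / 2] - pi
  phi[phi <= -pi / 2] <- phi[phi <= -pi / 2] + pi
  phi
}

#' Anisotropy profile below the horizon
#'
#' A full-width window with height one-fifth of the horizon-to-bottom
#' distance slides down row by row from the horizon to half the image
#' height. Per row, the anisotropy of the edge-pixel orientations inside the
#' window is computed; rows and values are then normalized to `[0, 1]`.
#'
#' @param edges Standard-mode binary edge map.
#' @param gray The grayscale image the edges came from (for gradient
#'   orientations).
#' @param horizon_y Horizon row (pixels).
#' @param cap Anisotropy cap for degenerate windows.
#' @return A list with `rows` (absolute window-top rows), `raw_values`,
#'   `values` (normalized), `rows_norm`, `window_height` and `carried`
#'   (logical; rows whose value was carried from the previous row).
#' @export
anisotropy_profile <- function(edges, gray, horizon_y, cap = 1e6) {
  H <- nrow(edges)
  hy <- as.integer(round(horizon_y))
  stopifnot(hy < H)
  hy <- max(hy, 1L)
  wh <- max(2L, as.integer(round((H - hy) / 5)))
  last <- as.integer(floor(H / 2))
  if (last <= hy) stop_rw("INSUFFICIENT_EDGES", "source_plane",
                          "horizon at or below half image height: no search band")
  rows <- hy:last
  phi <- edge_orientations(gray)
  phi[edges == 0] <- NA
  # per-image-row sums over edge pixels
  cnt <- rowSums(!is.na(phi))
  s1 <- rowSums(phi, na.rm = TRUE)
  s2 <- rowSums(phi^2, na.rm = TRUE)
  cum <- function(v) c(0, cumsum(v))
  C <- cum(cnt); S1 <- cum(s1); S2 <- cum(s2)
  top <- rows; bot <- pmin(rows + wh - 1L, H)
  n <- C[bot + 1L] - C[top]
  m1 <- (S1[bot + 1L] - S1[top])
  m2 <- (S2[bot + 1L] - S2[top])
  A <- rep(NA_real_, length(rows)); carried <- logical(length(rows))
  for (i in seq_along(rows)) {
    if (n[i] >= 2) {
      v <- m2[i] / n[i] - (m1[i] / n[i])^2
      A[i] <- if (v < 1e-6) cap else 1 / v
    } else {
      A[i] <- if (i > 1) A[i - 1] else NA_real_
      carried[i] <- TRUE
    }
  }
  if (all(is.na(A))) stop_rw("INSUFFICIENT_EDGES", "source_plane",
                             "no window in the search band contains edges")
  # leading windows with no edges: backfill from the first measured value so
  # they do not distort the normalization
  first_ok <- which(!is.na(A))[1]
  if (first_ok > 1) { A[seq_len(first_ok - 1)] <- A[first_ok]; carried[seq_len(first_ok - 1)] <- TRUE }
  rng <- range(A)
  vals <- if (diff(rng) > 0) (A - rng[1]) / diff(rng) else rep(0, length(A))
  rows_norm <- if (length(rows) > 1) (rows - rows[1]) / (rows[length(rows)] - rows[1]) else 0
  list(rows = rows, raw_values = A, values = vals, rows_norm = rows_norm,
       window_height = wh, carried = carried)
}

#' Select the anisotropy index
#'
#' The profile is smoothed with a centred moving average, and the first row
#' (from the horizon downward) where the discrete derivative in normalized
#' coordinates reaches -1 is returned. If the derivative never reaches -1,
#' the row of the minimum derivative is returned and flagged.
#'
#' @param profile Result of [anisotropy_profile()].
#' @param smooth_window Minimum moving-average window (rows). Because
#'   consecutive windows share almost all their pixels, profile noise is
#'   correlated over tens of rows; the effective window and the derivative
#'   stencil therefore scale with the profile length (window ~ n/4, stencil
#'   ~ n/16), bounded below by `smooth_window` and 1.
#' @return A list with `row` (absolute image row) and `fallback` (logical).
#' @export
select_anisotropy_index <- function(profile, smooth_window = 5L) {
  n <- length(profile$rows)
  stopifnot(n >= 5)
  w <- max(smooth_window, 2L * (as.integer(n / 8)) + 1L)
  k <- max(1L, as.integer(round(n / 16)))
  a <- smooth_ma(profile$values, w)
  r <- profile$rows_norm
  d <- rep(NA_real_, n)
  i <- (k + 1):(n - k)
  d[i] <- (a[i + k] - a[i - k]) / (r[i + k] - r[i - k])
  hit <- which(d <= -1)
  if (length(hit)) {
    # the rapid-loss zone is the first contiguous run of derivative <= -1;
    # everything above its lower edge is too distant to transform reliably,
    # so the index is the first row BELOW that run
    run_end <- hit[1]
    while (run_end + 1 <= n && !is.na(d[run_end + 1]) && d[run_end + 1] <= -1)
      run_end <- run_end + 1
    idx <- min(run_end + 1, n)
    return(list(row = profile$rows[idx], fallback = FALSE))
  }
  list(row = profile$rows[which.min(d)], fallback = TRUE)
}

smooth_ma <- function(v, w) {
  r <- (w - 1L) %/% 2L
  n <- length(v)
  cs <- c(0, cumsum(v))
  i1 <- pmax(seq_len(n) - r, 1L); i2 <- pmin(seq_len(n) + r, n)
  (cs[i2 + 1L] - cs[i1]) / (i2 - i1 + 1L)
}

#' Define the source plane
#'
#' The source plane spans the full image width from the anisotropy index down
#' to the bottom edge; its bottom corners are the image's own bottom corners.
#'
#' @param img Raster (roll-removed).
#' @param index Anisotropy index (top row of the plane, pixels).
#' @param horizon_y Horizon row, for the ordering check.
#' @return A list with `quad` (4 x 2 corners in image coordinates),
#'   `top_row`, and `image` (the cropped plane raster).
#' @export
define_source_plane <- function(img, index, horizon_y = -Inf) {
  H <- nrow(img); W <- ncol(img)
  index <- as.integer(round(index))
  if (index <= horizon_y) stop_rw("INSUFFICIENT_EDGES", "source_plane",
                                  "anisotropy index at or above the horizon")
  stopifnot(index > 0, index < H)
  # plane-local coordinates: y_local = y_global - index, height H - index
  crop <- if (is.matrix(img)) img[(index + 1L):H, ] else img[(index + 1L):H, , , drop = FALSE]
  list(quad = quad(c(0, index), c(W, index), c(W, H), c(0, H)),
       top_row = index, image = crop)
}
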