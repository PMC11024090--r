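# Brute-force inverse-perspective mapping. The perspective grid is drawn on
# the source plane in a reserved hue; the compression factor is stepped down
# from 1 and, at each step, the plane is warped and the angle between the two
# warped grid lines re-measured in the image. The search halts when the grid
# measures 90 degrees: the vanishing line has become parallel to the world
# depth axis and the perspective distortion is gone.

#' Draw the perspective grid on the source plane
#'
#' Rasterizes both grid lines in a reserved saturated color (default pure
#' yellow), 3 px thick, on a copy of the plane. Grid coordinates are given in
#' the full-image frame and re-offset to plane-local coordinates. Lines are
#' clipped to the canvas; a grid entirely outside the plane is an error.
#'
#' @param plane Source-plane RGB raster.
#' @param grid Result of [build_perspective_grid()] (full-image coordinates).
#' @param top_row Plane top row in the full image (the anisotropy index).
#' @param config Pipeline configuration.
#' @return The plane with the grid drawn.
#' @export
overlay_grid <- function(plane, grid, top_row = 0, config = rw_config()) {
  stopifnot(length(dim(plane)) == 3)
  H <- nrow(plane); W <- ncol(plane)
  out <- plane
  for (seg in list(grid$vanishing_line, grid$horizontal_line)) {
    y1 <- seg$y1 - top_row; y2 <- seg$y2 - top_row
    if (max(y1, y2) < 1 || min(y1, y2) > H || max(seg$x1, seg$x2) < 1 || min(seg$x1, seg$x2) > W)
      stop("grid line lies entirely outside the source plane")
    out <- draw_segment(out, seg$x1, y1, seg$x2, y2,
                        config$grid_color, config$grid_thickness)
  }
  out
}

draw_segment <- function(img, x1, y1, x2, y2, color, thickness) {
  H <- nrow(img); W <- ncol(img)
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  t <- seq(0, 1, length.out = max(2L, ceiling(len * 3)))
  xs <- round(x1 + t * (x2 - x1)); ys <- round(y1 + t * (y2 - y1))
  r <- (thickness - 1L) %/% 2L
  off <- expand.grid(dr = -r:r, dc = -r:r)
  for (k in seq_len(nrow(off))) {
    xx <- xs + off$dc[k]; yy <- ys + off$dr[k]
    ok <- xx >= 1 & xx <= W & yy >= 1 & yy <= H
    if (!any(ok)) next
    idx <- cbind(yy[ok], xx[ok])
    for (ch in 1:3) img[cbind(idx, ch)] <- color[ch]
  }
  img
}

# Segment the reserved grid color in HSV space.
grid_mask <- function(img, config) {
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  cand <- which(r > 0.55 & g > 0.55 & b < 0.6)  # cheap pre-filter
  mask <- matrix(0L, nrow(img), ncol(img))
  if (!length(cand)) return(mask)
  hsv <- rgb2hsv(rbind(r[cand], g[cand], b[cand]) * 255, maxColorValue = 255)
  target_h <- rgb2hsv(matrix(config$grid_color * 255, 3), maxColorValue = 255)[1]
  dh <- abs(hsv[1, ] - target_h)
  dh <- pmin(dh, 1 - dh)
  ok <- dh <= config$hue_tol & hsv[2, ] >= config$sat_min & hsv[3, ] >= config$val_min
  mask[cand[ok]] <- 1L
  mask
}

# Orientation (degrees in [0, 180)) of a point set via total least squares
# (principal axis of the scatter).
tls_orientation <- function(x, y) {
  cx <- x - mean(x); cy <- y - mean(y)
  Sxx <- sum(cx^2); Syy <- sum(cy^2); Sxy <- sum(cx * cy)
  ang <- 0.5 * atan2(2 * Sxy, Sxx - Syy)
  (ang * 180 / pi) %% 180
}

#' Measure the perspective-grid angle in a warped image
#'
#' Segments the reserved grid color in HSV space, applies morphological
#' closing, detects the two dominant line structures with a standard Hough
#' transform, assigns mask pixels to the nearer line (two-group clustering),
#' refines each group's orientation by total least squares, and returns the
#' acute angle between the group orientations.
#'
#' @param warped Warped RGB raster containing the drawn grid.
#' @param config Pipeline configuration.
#' @return The acute angle in degrees, with attribute `signed` (the oriented
#'   angle of the vanishing group relative to the horizontal group, in
#'   `(0, 180)`).
#' @export
measure_grid_angle <- function(warped, config = rw_config()) {
  mask <- grid_mask(warped, config)
  mask <- close_box(mask, 2L)
  idx <- which(mask == 1L)
  if (length(idx) < 20) stop_rw("SEARCH_NON_CONVERGENCE", "search",
                                "grid lost: too few reserved-color pixels")
  y <- (idx - 1L) %% nrow(mask) + 1L
  x <- (idx - 1L) %/% nrow(mask) + 1L
  lines <- dominant_two_lines(x, y)
  if (is.null(lines)) stop_rw("SEARCH_NON_CONVERGENCE", "search",
                              "grid lost: fewer than two line groups found")
  # identify the horizontal group as the orientation closer to 0/180
  dev_h <- pmin(lines$theta, 180 - lines$theta)
  hi <- which.min(dev_h)
  th_h <- lines$theta[hi]; th_v <- lines$theta[-hi]
  signed <- (th_v - th_h) %% 180
  acute <- min(signed, 180 - signed)
  attr(acute, "signed") <- signed
  acute
}

# Two dominant lines: coarse standard Hough for the strongest line, removal
# of its pixels, a second Hough on the remainder, then alternating
# assignment and total-least-squares refinement of both groups.
dominant_two_lines <- function(x, y) {
  th <- seq(0, pi, length.out = 181)[-181]
  ct <- cos(th); st <- sin(th)
  hough_peak <- function(idx) {
    rho <- outer(x[idx], ct) + outer(y[idx], st)
    rr <- round(rho / 3)  # 3-px rho bins
    best <- c(0, 0, 0)
    for (k in seq_along(th)) {
      tb <- tabulate(rr[, k] - min(rr[, k]) + 1L)
      m <- which.max(tb)
      if (tb[m] > best[1]) best <- c(tb[m], k, (m + min(rr[, k]) - 1) * 3)
    }
    best  # (votes, theta index, rho)
  }
  all_idx <- seq_along(x)
  p1 <- hough_peak(all_idx)
  d1 <- abs(x * ct[p1[2]] + y * st[p1[2]] - p1[3])
  rest <- which(d1 > 4)
  if (length(rest) < 10) return(NULL)
  p2 <- hough_peak(rest)
  if (p2[1] < 10) return(NULL)
  line_par <- rbind(c(th[p1[2]], p1[3]), c(th[p2[2]], p2[3]))
  for (iter in 1:3) {
    dd <- vapply(1:2, function(i)
      abs(x * cos(line_par[i, 1]) + y * sin(line_par[i, 1]) - line_par[i, 2]),
      numeric(length(x)))
    g1 <- dd[, 1] <= dd[, 2]
    if (sum(g1) < 5 || sum(!g1) < 5) return(NULL)
    t1 <- tls_orientation(x[g1], y[g1])
    t2 <- tls_orientation(x[!g1], y[!g1])
    upd <- function(t, sel) {
      nrm <- (t + 90) * pi / 180
      c(nrm %% pi, mean(x[sel] * cos(nrm %% pi) + y[sel] * sin(nrm %% pi)))
    }
    line_par <- rbind(upd(t1, g1), upd(t2, !g1))
  }
  list(theta = c(t1, t2), n = c(sum(g1), sum(!g1)))
}

#' Brute-force search for the compression factor
#'
#' Iterates `x_cf = 1 - step, 1 - 2 step, ...`, and per iteration builds the
#' destination trapezoid (far corners pinned to the top-source corners,
#' near-corner separation `x_cf * w`), fits the homography, warps the
#' grid-bearing plane, and measures the grid angle. The search halts when the
#' measured angle is within `tol` of 90 degrees; if consecutive iterates
#' bracket 90, the closer one is kept.
#'
#' @param plane_with_grid Source plane with the grid drawn ([overlay_grid()]).
#' @param w,h Source-plane width and height in pixels.
#' @param step Compression-factor decrement (0 < step <= 0.01).
#' @param tol Angle tolerance in degrees.
#' @param config Pipeline configuration.
#' @return A list of class `rw_search`: `x_cf`, `grid_angle_at_stop`,
#'   `homography`, `transformed` (the final warp of the grid-bearing plane),
#'   `n_iterations`, `converged`, `trace` (data frame of `x_cf`, signed and
#'   acute angles).
#' @export
search_compression_factor <- function(plane_with_grid, w, h,
                                      step = NULL, tol = NULL,
                                      config = rw_config()) {
  step <- step %||% config$search_step
  tol <- tol %||% config$angle_tol
  stopifnot(step > 0, step <= 0.01)
  src <- quad(c(0, 0), c(w, 0), c(w, h), c(0, h))
  xs <- seq(1 - step, step, by = -step)
  trace <- list()
  prev <- NULL
  n_fail <- 0L
  for (i in seq_along(xs)) {
    x_cf <- xs[i]
    cur <- tryCatch(eval_xcf(plane_with_grid, src, w, h, x_cf, config),
                    error = function(e) e)
    if (inherits(cur, "error")) {
      # isolated measurement dropouts (aliasing of the thinning grid lines)
      # are skipped; a persistent loss aborts the search
      n_fail <- n_fail + 1L
      if (n_fail >= 25L) stop_rw("SEARCH_NON_CONVERGENCE", "search",
                                 "grid lost for 25 consecutive iterations")
      trace[[i]] <- c(x_cf = x_cf, signed = NA_real_, acute = NA_real_)
      next
    }
    n_fail <- 0L
    trace[[i]] <- c(x_cf = x_cf, signed = cur$signed, acute = cur$acute)
    if (abs(cur$signed - 90) <= tol) {
      # ninety degrees detected: keep stepping while the angle still closes
      # in, so the saved iterate is the one closest to 90 (this also covers
      # the case where consecutive steps bracket 90: the closer one wins)
      if (is.null(prev) || abs(prev$res$signed - 90) >= abs(cur$signed - 90)) {
        prev <- list(res = cur, x_cf = x_cf, i = i)
        next
      }
      return(search_result(prev$res, prev$x_cf, i, TRUE, trace))
    }
    if (!is.null(prev) && abs(prev$res$signed - 90) <= tol) {
      # left the tolerance band: the best in-band iterate was the minimizer
      return(search_result(prev$res, prev$x_cf, i, TRUE, trace))
    }
    if (!is.null(prev) && sign(prev$res$signed - 90) != sign(cur$signed - 90) &&
        abs(prev$res$signed - 90) <= 5 && abs(cur$signed - 90) <= 5) {
      # bracketed 90 between consecutive steps: keep the closer iterate
      if (abs(prev$res$signed - 90) <= abs(cur$signed - 90)) {
        return(search_result(prev$res, prev$x_cf, i, TRUE, trace))
      }
      return(search_result(cur, x_cf, i, TRUE, trace))
    }
    prev <- list(res = cur, x_cf = x_cf)
  }
  if (!is.null(prev) && abs(prev$res$signed - 90) <= tol) {
    return(search_result(prev$res, prev$x_cf, length(xs), TRUE, trace))
  }
  tr <- do.call(rbind, trace)
  last_ok <- tr[max(which(!is.na(tr[, "signed"]))), ]
  diag <- if (last_ok["signed"] > 90) "over-corrected" else "under-corrected"
  stop_rw("SEARCH_NON_CONVERGENCE", "search",
          sprintf("compression-factor space exhausted (%s; final angle %.2f)",
                  diag, last_ok["acute"]))
}

eval_xcf <- function(plane_with_grid, src, w, h, x_cf, config) {
  dc <- destination_corners(w, h, x_cf)
  dst <- quad(c(0, 0), c(w, 0), dc$C_R, dc$C_L)
  Hm <- fit_homography(src, dst)
  warped <- warp_image(plane_with_grid, Hm, c(w, h))
  a <- measure_grid_angle(warped, config)
  list(acute = as.numeric(a), signed = attr(a, "signed"),
       homography = Hm, warped = warped)
}

search_result <- function(res, x_cf, n_iter, converged, trace) {
  tr <- as.data.frame(do.call(rbind, trace))
  structure(list(x_cf = x_cf, grid_angle_at_stop = res$acute,
                 signed_angle = res$signed, homography = res$homography,
                 transformed = res$warped, n_iterations = n_iter,
                 converged = converged, trace = tr),
            class = "rw_search")
}
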