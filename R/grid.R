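# Perspective-grid detection: probabilistic Hough segments, logical-angle and
# side/sign filtering, candidate vanishing points from left-right segment
# intersections, the overall vanishing point as their mean, and the
# highest-ranking vanishing line (minimum perpendicular distance from the
# overall vanishing point) paired with a horizontal line through its
# y-midpoint.

#' Detect line segments in an edge map
#'
#' Probabilistic Hough-line transform with deliberately relaxed constraints
#' (low vote threshold, short minimum length) so that scenes with sparse
#' structure still yield many small segments. Edges above the horizon are
#' expected to have been zeroed by the caller.
#'
#' @param edges Binary edge matrix.
#' @param config Pipeline configuration.
#' @return A data frame with columns `x1, y1, x2, y2`.
#' @export
detect_line_segments <- function(edges, config = rw_config()) {
  idx <- which(edges == 1)
  if (!length(idx)) return(data.frame(x1 = numeric(), y1 = numeric(),
                                      x2 = numeric(), y2 = numeric()))
  r <- (idx - 1L) %% nrow(edges) + 1L
  c <- (idx - 1L) %/% nrow(edges) + 1L
  ord <- withr::with_seed(config$seed, sample.int(length(idx)))
  segs <- hough_prob_cpp(r, c, nrow(edges), ncol(edges), 180L,
                         as.integer(config$hough_threshold),
                         as.integer(config$hough_min_len),
                         as.integer(config$hough_max_gap), ord)
  segs <- as.data.frame(segs)
  # refine each segment against the underlying edge pixels: Hough endpoints
  # are pixel-quantized, and a total-least-squares re-fit of the inliers
  # removes most of the direction noise
  refine_segments(segs, c, r)
}

refine_segments <- function(segs, ex, ey, band = 2.5) {
  if (!nrow(segs)) return(segs)
  for (i in seq_len(nrow(segs))) {
    x1 <- segs$x1[i]; y1 <- segs$y1[i]; x2 <- segs$x2[i]; y2 <- segs$y2[i]
    len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    ux <- (x2 - x1) / len; uy <- (y2 - y1) / len
    dx <- ex - x1; dy <- ey - y1
    along <- dx * ux + dy * uy
    perp <- -dx * uy + dy * ux
    sel <- abs(perp) <= band & along >= -5 & along <= len + 5
    if (sum(sel) < 10) next
    mx <- mean(ex[sel]); my <- mean(ey[sel])
    cx <- ex[sel] - mx; cy <- ey[sel] - my
    ang <- 0.5 * atan2(2 * sum(cx * cy), sum(cx^2) - sum(cy^2))
    vx <- cos(ang); vy <- sin(ang)
    # re-anchor the endpoints by projecting the originals onto the new line
    t1 <- (x1 - mx) * vx + (y1 - my) * vy
    t2 <- (x2 - mx) * vx + (y2 - my) * vy
    segs$x1[i] <- mx + t1 * vx; segs$y1[i] <- my + t1 * vy
    segs$x2[i] <- mx + t2 * vx; segs$y2[i] <- my + t2 * vy
  }
  segs
}

seg_slope <- function(segs) (segs$y2 - segs$y1) / (segs$x2 - segs$x1)
seg_angle_deg <- function(segs) {
  atan2(abs(segs$y2 - segs$y1), abs(segs$x2 - segs$x1)) * 180 / pi
}

# Minimum absolute segment angle, interpolated in the horizon intercept: a
# horizon in the top third of the frame implies steeply converging vanishing
# lines (25 deg), around the middle third shallow ones (10 deg).
logical_angle_min <- function(intercept, H, config) {
  lo <- H / 3; hi <- 2 * H / 3
  t <- (intercept - lo) / (hi - lo)
  t <- min(max(t, 0), 1)
  config$angle_min_high + t * (config$angle_min_low - config$angle_min_high)
}

#' Filter detected segments into candidate vanishing lines
#'
#' Applies (i) the logical-angle filter keyed to the horizon intercept,
#' (ii) a left/right split at the segment x-midpoint relative to the image
#' midline (ties go left), (iii) the slope sign rule (right-side lines keep
#' positive slope in y-down coordinates, left-side negative), and (iv) seeded
#' random downsampling of the larger group to the size of the smaller one.
#'
#' @param segments Data frame from [detect_line_segments()].
#' @param horizon Horizon as an [rw_line()].
#' @param width,height Image dimensions in pixels (the height drives the
#'   logical-angle interpolation).
#' @param config Pipeline configuration.
#' @return A list with data frames `left` and `right` (balanced sizes) and
#'   `all` (both sides before downsampling).
#' @export
filter_candidate_lines <- function(segments, horizon, width, height,
                                   config = rw_config()) {
  if (nrow(segments)) {
    ang <- seg_angle_deg(segments)
    amin <- logical_angle_min(horizon$intercept, height, config)
    keep <- is.finite(ang) & ang >= amin & ang <= config$angle_max
    segments <- segments[keep, , drop = FALSE]
  }
  if (nrow(segments)) {
    mid <- (segments$x1 + segments$x2) / 2
    sl <- seg_slope(segments)
    is_left <- mid <= width / 2
    left <- segments[is_left & sl < 0, , drop = FALSE]
    right <- segments[!is_left & sl > 0, , drop = FALSE]
  } else {
    left <- right <- segments
  }
  if (!nrow(left) || !nrow(right))
    stop_rw("NO_CANDIDATE_LINES", "grid", "no candidate vanishing lines on one side")
  all <- rbind(left, right)
  n <- min(nrow(left), nrow(right))
  ds <- function(d) if (nrow(d) > n)
    d[withr::with_seed(config$seed, sort(sample.int(nrow(d), n))), , drop = FALSE] else d
  list(left = ds(left), right = ds(right), all = all)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

seg_line <- function(seg) {
  m <- (seg$y2 - seg$y1) / (seg$x2 - seg$x1)
  list(slope = m, intercept = seg$y1 - m * seg$x1)
}

#' Candidate vanishing points from left-right line intersections
#'
#' Intersections of every unique left-right pair, kept only if they lie
#' within a vertical band around the horizon line and within the central
#' quarter of the image width.
#'
#' @param left,right Candidate segment data frames.
#' @param horizon Horizon [rw_line()].
#' @param width,height Image dimensions in pixels.
#' @param config Pipeline configuration.
#' @return An n x 2 matrix of `(x, y)` candidate points.
#' @export
candidate_vanishing_points <- function(left, right, horizon, width, height,
                                       config = rw_config()) {
  stopifnot(nrow(left) > 0, nrow(right) > 0)
  L <- seg_line(left); R <- seg_line(right)
  ml <- rep(L$slope, times = nrow(right)); bl <- rep(L$intercept, times = nrow(right))
  mr <- rep(R$slope, each = nrow(left)); br <- rep(R$intercept, each = nrow(left))
  dm <- ml - mr
  ok <- abs(dm) > 1e-9
  x <- (br[ok] - bl[ok]) / dm[ok]
  y <- ml[ok] * x + bl[ok]
  band <- config$vp_band_frac * height
  keep <- abs(y - line_y(horizon, x)) <= band &
    x >= config$vp_x_window[1] * width & x <= config$vp_x_window[2] * width
  pts <- cbind(x = x[keep], y = y[keep])
  if (!nrow(pts)) stop_rw("NO_VANISHING_POINT", "grid",
                          "no intersections along the horizon near the image centre")
  pts
}

#' Overall vanishing point
#' @param candidates n x 2 matrix of candidate vanishing points.
#' @return Length-2 `(x, y)`.
#' @export
overall_vanishing_point <- function(candidates) {
  if (is.null(dim(candidates))) candidates <- matrix(candidates, 1)
  if (!nrow(candidates)) stop_rw("NO_VANISHING_POINT", "grid", "no candidate points")
  colMeans(candidates)
}

# Perpendicular distance from point p to the infinite line through a segment.
perp_distance <- function(seg, p) {
  a <- seg$y2 - seg$y1
  b <- -(seg$x2 - seg$x1)
  c <- -(a * seg$x1 + b * seg$y1)
  abs(a * p[1] + b * p[2] + c) / sqrt(a^2 + b^2)
}

#' Select the highest-ranking vanishing line
#'
#' From the candidate pool, excludes segments whose y-midpoint lies above the
#' anisotropy index (the line must lie on the source plane), then selects the
#' segment whose infinite line passes closest to the overall vanishing point
#' (ties broken by input order). Segments shorter than the minimum length are
#' extended symmetrically about their midpoint.
#'
#' @param segments Candidate segment data frame (both sides).
#' @param vp Overall vanishing point `(x, y)`.
#' @param anisotropy_index Top row of the source plane.
#' @param config Pipeline configuration.
#' @return A one-row segment data frame (columns `x1, y1, x2, y2`).
#' @export
select_vanishing_line <- function(segments, vp, anisotropy_index,
                                  config = rw_config()) {
  ymid <- (segments$y1 + segments$y2) / 2
  pool <- segments[ymid > anisotropy_index, , drop = FALSE]
  if (!nrow(pool)) stop_rw("NO_CANDIDATE_LINES", "grid",
                           "all candidate lines lie above the anisotropy index")
  d <- perp_distance(pool, vp)
  # among candidates whose lines pass (nearly) equally close to the
  # vanishing point, a longer segment pins the direction more precisely
  len <- sqrt((pool$x2 - pool$x1)^2 + (pool$y2 - pool$y1)^2)
  elig <- which(d <= min(d) + 3)
  best <- pool[elig[which.max(len[elig])], , drop = FALSE]
  extend_segment(best, config$min_vline_len)
}

extend_segment <- function(seg, min_len) {
  len <- sqrt((seg$x2 - seg$x1)^2 + (seg$y2 - seg$y1)^2)
  if (len >= min_len) return(seg)
  mx <- (seg$x1 + seg$x2) / 2; my <- (seg$y1 + seg$y2) / 2
  ux <- (seg$x2 - seg$x1) / len; uy <- (seg$y2 - seg$y1) / len
  data.frame(x1 = mx - ux * min_len / 2, y1 = my - uy * min_len / 2,
             x2 = mx + ux * min_len / 2, y2 = my + uy * min_len / 2)
}

# Slide a segment along its own direction (and clip if necessary) so that it
# lies inside the box x in [0, w], y in [ytop, ybot]: the drawn vanishing
# line must stay visible on the source plane throughout the search.
fit_segment_to_box <- function(seg, w, ytop, ybot) {
  len <- sqrt((seg$x2 - seg$x1)^2 + (seg$y2 - seg$y1)^2)
  ux <- (seg$x2 - seg$x1) / len; uy <- (seg$y2 - seg$y1) / len
  # param t along the infinite line from (x1, y1)
  tr <- c(-Inf, Inf)
  clip1 <- function(p, u, lo, hi, tr) {
    if (abs(u) < 1e-12) { if (p < lo || p > hi) return(NULL); return(tr) }
    tt <- sort(c((lo - p) / u, (hi - p) / u))
    c(max(tr[1], tt[1]), min(tr[2], tt[2]))
  }
  tr <- clip1(seg$x1, ux, 0, w, tr)
  if (!is.null(tr)) tr <- clip1(seg$y1, uy, ytop, ybot, tr)
  if (is.null(tr) || tr[1] >= tr[2]) return(seg)  # line misses the box; keep as-is
  have <- tr[2] - tr[1]
  want <- min(len, have)
  # centre the retained span on the original segment, clamped into the box
  t0 <- max(tr[1], min((0 + len) / 2 - want / 2, tr[2] - want))
  data.frame(x1 = seg$x1 + ux * t0, y1 = seg$y1 + uy * t0,
             x2 = seg$x1 + ux * (t0 + want), y2 = seg$y1 + uy * (t0 + want))
}

#' Build the axis-aligned perspective grid
#'
#' Pairs the selected vanishing line with a horizontal line spanning the full
#' image width through the vanishing line's y-coordinate midpoint.
#'
#' @param vline One-row segment data frame (the selected vanishing line).
#' @param width Image width in pixels.
#' @param vp Overall vanishing point.
#' @return A list with `vanishing_line`, `horizontal_line` (segments) and
#'   `vp`.
#' @export
build_perspective_grid <- function(vline, width, vp) {
  ymid <- (vline$y1 + vline$y2) / 2
  list(vanishing_line = vline,
       horizontal_line = data.frame(x1 = 0, y1 = ymid, x2 = width, y2 = ymid),
       vp = vp)
}
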