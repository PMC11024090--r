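# Synthetic fixtures: a pinhole camera over a textured ground plane, with a
# low-texture water column above the analytic horizon, optional surface
# clutter, optional lens distortion, and exported ground truth (horizon,
# vanishing point, top-down homography, true compression factor, marker
# coordinates). World frame: ground plane z = 0, x right, y away from the
# camera, z up; camera at (0, 0, camera_height). The camera is pitched down
# about its x-axis, then rolled about the optical axis. All randomness is
# seeded; identical seeds give identical scenes.

deg2rad <- function(d) d * pi / 180

#' Define a synthetic camera pose over the reef plane
#'
#' @param camera_height Camera height above the plane, world units.
#' @param pitch Degrees below horizontal (0, 90).
#' @param roll Camera roll in degrees, |roll| < 45.
#' @param yaw Heading in degrees (0 = straight along +y).
#' @param cam Optional `rw_camera` intrinsics; defaults to a wide-angle
#'   pinhole with zero distortion sized for `size`.
#' @param size `c(width, height)` of the rendered image in pixels.
#' @return A list of class `rw_pose`.
#' @export
scene_pose <- function(camera_height = 2, pitch = 20, roll = 5, yaw = 0,
                       cam = NULL, size = c(1600, 1200)) {
  stopifnot(pitch > 0, pitch < 90, abs(roll) < 45)
  W <- size[1]; H <- size[2]
  if (is.null(cam)) {
    f <- 0.47 * W
    cam <- camera_model(f, f, (W + 1) / 2, (H + 1) / 2, image_size = c(W, H),
                        camera_name = "synthetic")
  }
  B <- rbind(c(1, 0, 0), c(0, 0, -1), c(0, 1, 0))  # axes: cam x=X, y=-Z, z=Y
  p <- deg2rad(pitch); r <- deg2rad(roll); yw <- deg2rad(yaw)
  Rx <- rbind(c(1, 0, 0), c(0, cos(p), -sin(p)), c(0, sin(p), cos(p)))
  Rz <- rbind(c(cos(r), -sin(r), 0), c(sin(r), cos(r), 0), c(0, 0, 1))
  Rw <- rbind(c(cos(yw), -sin(yw), 0), c(sin(yw), cos(yw), 0), c(0, 0, 1))
  R <- Rz %*% Rx %*% B %*% Rw
  structure(list(camera_height = camera_height, pitch = pitch, roll = roll,
                 yaw = yaw, cam = cam, size = size, R = R,
                 C = c(0, 0, camera_height)),
            class = "rw_pose")
}

# Project world points (n x 3) to pixel coordinates; NA when behind camera.
project_world <- function(pose, pw) {
  if (is.null(dim(pw))) pw <- matrix(pw, 1)
  pc <- t(pose$R %*% (t(pw) - pose$C))
  vis <- pc[, 3] > 1e-9
  xy <- cbind(pc[, 1] / pc[, 3], pc[, 2] / pc[, 3])
  px <- normalized_to_pixel(distort_normalized(xy, pose$cam), pose$cam)
  px[!vis, ] <- NA
  px
}

# Back-project pixel points to the ground plane (zero-distortion rays unless
# the pose camera carries distortion). Returns n x 2 world (X, Y); NA for
# rays that do not hit the plane.
#' Back-project image points to the ground plane
#' @param pose An `rw_pose`.
#' @param pts n x 2 pixel coordinates.
#' @return n x 2 world coordinates on the plane.
#' @export
back_project <- function(pose, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, 1)
  xy <- pixel_to_normalized(pts, pose$cam)
  if (any(c(pose$cam$k1, pose$cam$k2, pose$cam$k3, pose$cam$p1, pose$cam$p2) != 0))
    xy <- undistort_normalized(xy, pose$cam)
  dw <- t(pose$R) %*% rbind(xy[, 1], xy[, 2], 1)
  hit <- dw[3, ] < -1e-12
  tt <- ifelse(hit, pose$camera_height / (-dw[3, ]), NA_real_)
  cbind(X = tt * dw[1, ], Y = tt * dw[2, ])
}

# Analytic horizon: the image of the plane's line at infinity, through the
# vanishing points of the world x and y directions.
analytic_horizon <- function(pose) {
  K <- rbind(c(pose$cam$fx, 0, pose$cam$cx), c(0, pose$cam$fy, pose$cam$cy), c(0, 0, 1))
  p1 <- K %*% pose$R %*% c(1, 0, 0)
  p2 <- K %*% pose$R %*% c(0, 1, 0)
  l <- pracma::cross(as.numeric(p1), as.numeric(p2))
  rw_line(-l[1] / l[2], -l[3] / l[2])
}

analytic_vp <- function(pose) {
  d <- pose$R %*% c(sin(deg2rad(pose$yaw)), cos(deg2rad(pose$yaw)), 0)
  c(x = pose$cam$fx * d[1] / d[3] + pose$cam$cx,
    y = pose$cam$fy * d[2] / d[3] + pose$cam$cy)
}

# Homography mapping world plane (X, Y, 1) to pixel coordinates, and its
# inverse (the true top-down map), normalized to [3,3] = 1.
analytic_topdown <- function(pose) {
  K <- rbind(c(pose$cam$fx, 0, pose$cam$cx), c(0, pose$cam$fy, pose$cam$cy), c(0, 0, 1))
  M <- cbind(pose$R[, 1], pose$R[, 2], -pose$R %*% pose$C)
  Hw <- K %*% M
  Ht <- solve(Hw)
  Ht / Ht[3, 3]
}

#' True compression factor for a source plane
#'
#' The ratio of the ground-plane width spanned by the bottom image row to the
#' width spanned by the source-plane top row, both obtained by
#' back-projecting the row endpoints.
#'
#' @param pose An `rw_pose`.
#' @param top_pts,bottom_pts 2 x 2 matrices: the endpoints (left, right) of
#'   the source-plane top and bottom borders in original image coordinates.
#' @return A scalar in `(0, 1)`.
#' @export
x_cf_truth <- function(pose, top_pts, bottom_pts) {
  wt <- back_project(pose, top_pts)
  wb <- back_project(pose, bottom_pts)
  sqrt(sum((wb[2, ] - wb[1, ])^2)) / sqrt(sum((wt[2, ] - wt[1, ])^2))
}

# Seeded lattice value noise on world coordinates.
vnoise <- function(x, y, seed) {
  h <- function(i, j) {
    v <- sin(i * 127.1 + j * 311.7 + seed * 74.7) * 43758.5453
    v - floor(v)
  }
  xi <- floor(x); yi <- floor(y)
  fx <- x - xi; fy <- y - yi
  u <- fx * fx * (3 - 2 * fx); w <- fy * fy * (3 - 2 * fy)
  h(xi, yi) * (1 - u) * (1 - w) + h(xi + 1, yi) * u * (1 - w) +
    h(xi, yi + 1) * (1 - u) * w + h(xi + 1, yi + 1) * u * w
}

#' Default transect markers for a pose
#'
#' Five world-equal x-direction marker pairs at increasing distance from the
#' camera, plus ten markers equally spaced along the depth axis (nine equal
#' y-segments), mirroring a ground-truthed transect layout.
#'
#' @param pose An `rw_pose`.
#' @param x_sep World separation of each x pair.
#' @param y_step World spacing of the y-line markers.
#' @param y_near Nearest marker depth (world units).
#' @param y_far Farthest depth used for the x pairs.
#' @return A data frame with columns `X`, `Y`, `set` (`"x"` or `"y"`),
#'   `pair`.
#' @export
default_markers <- function(pose, x_sep = 0.8, y_step = 0.35,
                            y_near = 1.6, y_far = 4.5) {
  yx <- seq(y_near, y_far, length.out = 5)
  xpairs <- data.frame(X = c(rbind(-x_sep / 2, x_sep / 2)),
                       Y = rep(yx, each = 2),
                       set = "x", pair = rep(seq_len(5), each = 2))
  yline <- data.frame(X = 0.35, Y = y_near + y_step * (0:9),
                      set = "y", pair = seq_len(10))
  rbind(xpairs, yline)
}

#' Render a synthetic reefscape with ground truth
#'
#' The ground plane carries seeded elliptical "colony" blobs over two
#' octaves of value noise; the region above the analytic horizon is a
#' low-texture blue gradient (optionally with bright clutter blobs to
#' exercise water-column suppression). Markers are rendered as
#' high-contrast dots.
#'
#' @param pose An `rw_pose`.
#' @param texture_seed Integer seed for all texture and blob randomness.
#' @param n_blobs Number of colony blobs.
#' @param n_streaks Number of elongated groove/branch features (the straight
#'   structures whose images act as vanishing lines).
#' @param fog_len Haze attenuation length in camera heights.
#' @param clutter Add bright clutter above the horizon.
#' @param markers Data frame with columns `X`, `Y` (world coordinates), or
#'   `NULL` for none.
#' @return A list with `img` (H x W x 3 raster) and `truth`: `horizon`
#'   ([rw_line()]), `vp`, `H_topdown`, `markers` (world and image
#'   coordinates), and the `pose`.
#' @export
render_reefscape <- function(pose, texture_seed = 0, n_blobs = 900,
                             n_streaks = 150, fog_len = 60, clutter = FALSE, markers = NULL) {
  W <- pose$size[1]; H <- pose$size[2]
  cam <- pose$cam
  horizon <- analytic_horizon(pose)
  ends <- line_y(horizon, c(1, W))
  if (any(!is.finite(ends)) || any(ends < 2) || any(ends > H - 2))
    stop("fixture error: pose places the horizon off-frame")

  u <- rep(seq_len(W), each = H); v <- rep(seq_len(H), times = W)
  xy <- pixel_to_normalized(cbind(u, v), cam)
  if (any(c(cam$k1, cam$k2, cam$k3, cam$p1, cam$p2) != 0))
    xy <- undistort_normalized(xy, cam)
  dw <- t(pose$R) %*% rbind(xy[, 1], xy[, 2], 1)
  ground <- dw[3, ] < -1e-9
  tt <- pose$camera_height / (-dw[3, ])
  X <- tt * dw[1, ]; Y <- tt * dw[2, ]

  r <- g <- b <- numeric(W * H)
  # water column: vertical gradient, nearly featureless
  depth <- v / pmax(line_y(horizon, u), 2)
  r[!ground] <- 0.10 + 0.06 * depth[!ground]
  g[!ground] <- 0.24 + 0.10 * depth[!ground]
  b[!ground] <- 0.42 + 0.12 * depth[!ground]

  gi <- which(ground)
  # band-limit each noise octave at the pixel footprint (world units per
  # pixel = depth / focal length): imaging integrates over the footprint
  # rather than aliasing, so distant texture fades toward its mean
  # per-pixel ground footprint: horizontal ~ depth / f; vertical grows
  # quadratically with range because of the grazing view angle
  fph <- tt[gi] / cam$fx
  l2 <- X[gi]^2 + Y[gi]^2 + pose$camera_height^2
  fpv <- l2 / (pose$camera_height * cam$fy)
  fp <- pmax(fph, fpv)
  amp <- function(L) pmin(1, pmax(0, (L / fp - 3.5) / 2.5))
  # fractal texture: octaves spanning colony to rubble scales, so every depth
  # has structure at a detectable apparent size
  val <- rep(0.5, length(gi))
  for (k in -2:7) {
    L <- 0.05 * 2^k
    val <- val + 0.13 * (vnoise(X[gi] / L, Y[gi] / L, texture_seed + 10 + k) - 0.5) * amp(L)
  }
  r[gi] <- 0.20 + 0.58 * val
  g[gi] <- 0.18 + 0.50 * val
  b[gi] <- 0.14 + 0.36 * val
  valf <- rep(0.5, W * H); valf[gi] <- val  # fractal field, reused inside colonies

  # seeded colony blobs, placed uniformly in image space below the horizon.
  # Apparent (pixel) radii are drawn directly and converted to world radii at
  # each blob's depth: colonies of many physical sizes, with roughly uniform
  # image-space edge density at all depths (reef texture produces edges
  # everywhere below the horizon).
  blobs <- if (n_blobs == 0) data.frame() else withr::with_seed(texture_seed + 3, {
    pu <- runif(6 * n_blobs, 1, W); pv <- runif(6 * n_blobs, 1, H)
    ok <- pv > line_y(horizon, pu) + 0.02 * H
    pu <- pu[ok][seq_len(n_blobs)]; pv <- pv[ok][seq_len(n_blobs)]
    data.frame(u = pu, v = pv,
               r_px = exp(runif(n_blobs, log(5), log(25))),
               aspect = runif(n_blobs, 0.55, 1),
               ang = runif(n_blobs, 0, pi),
               shade = runif(n_blobs, -0.35, 0.4),
               hue = sample.int(3, n_blobs, replace = TRUE))
  })
  if (n_blobs > 0) {
    ctr <- back_project(pose, cbind(blobs$u, blobs$v))
    # camera-frame depth of each blob centre sets the pixel -> world scale
    pc <- t(pose$R %*% (t(cbind(ctr, 0)) - pose$C))
    blobs$r1 <- blobs$r_px * pc[, 3] / cam$fx
  }
  pal <- rbind(c(0.75, 0.62, 0.42), c(0.55, 0.62, 0.40), c(0.70, 0.52, 0.55))
  Xm <- matrix(X, H, W); Ym <- matrix(Y, H, W)
  rm <- matrix(r, H, W); gm <- matrix(g, H, W); bm <- matrix(b, H, W)
  grm <- matrix(ground, H, W); valm <- matrix(valf, H, W)
  for (i in seq_len(nrow(blobs))) {
    cxw <- ctr[i, 1]; cyw <- ctr[i, 2]
    if (!is.finite(cxw)) next
    r1 <- blobs$r1[i]; r2 <- r1 * blobs$aspect[i]
    corn <- as.matrix(expand.grid(X = cxw + c(-1.2, 1.2) * r1,
                                  Y = cyw + c(-1.2, 1.2) * r1))
    bb <- project_world(pose, cbind(corn, 0))
    if (anyNA(bb)) next
    c1 <- max(1L, floor(min(bb[, 1]))); c2 <- min(W, ceiling(max(bb[, 1])))
    r1i <- max(1L, floor(min(bb[, 2]))); r2i <- min(H, ceiling(max(bb[, 2])))
    if (c2 < c1 || r2i < r1i) next
    dx <- Xm[r1i:r2i, c1:c2] - cxw; dy <- Ym[r1i:r2i, c1:c2] - cyw
    ca <- cos(blobs$ang[i]); sa <- sin(blobs$ang[i])
    m <- ((dx * ca + dy * sa) / r1)^2 + ((-dx * sa + dy * ca) / r2)^2
    # fade colonies whose foreshortened apparent height falls below a few
    # pixels: a real camera blurs them out rather than drawing crisp slivers
    # (use the unclipped extent so border colonies are unaffected)
    fade <- min(1, max(0, (max(bb[, 2]) - min(bb[, 2]) - 4) / 6))
    wgt <- fade * pmin(pmax((1 - m) / 0.25, 0), 1) * grm[r1i:r2i, c1:c2]
    if (!any(wgt > 0)) next
    col <- clamp01(pal[blobs$hue[i], ] * (1 + blobs$shade[i]))
    tex <- 0.55 + 0.9 * valm[r1i:r2i, c1:c2]  # colonies keep internal texture
    rm[r1i:r2i, c1:c2] <- rm[r1i:r2i, c1:c2] * (1 - wgt) + col[1] * tex * wgt
    gm[r1i:r2i, c1:c2] <- gm[r1i:r2i, c1:c2] * (1 - wgt) + col[2] * tex * wgt
    bm[r1i:r2i, c1:c2] <- bm[r1i:r2i, c1:c2] * (1 - wgt) + col[3] * tex * wgt
  }

  # elongated world-space features (sand grooves, rubble channels, branching
  # colonies): the straight structures whose images converge toward the
  # vanishing point. A fraction runs roughly shore-normal (spur-and-groove),
  # the rest are oriented at random.
  if (n_streaks > 0) {
    st <- withr::with_seed(texture_seed + 5, {
      pu <- runif(4 * n_streaks, 1, W); pv <- runif(4 * n_streaks, 1, H)
      ok <- pv > line_y(horizon, pu) + 0.03 * H
      pu <- pu[ok][seq_len(n_streaks)]; pv <- pv[ok][seq_len(n_streaks)]
      aligned <- runif(n_streaks) < 0.6
      data.frame(u = pu, v = pv,
                 phi = ifelse(aligned, rnorm(n_streaks, 0, 1.5),
                              runif(n_streaks, 0, 180)) * pi / 180,
                 len = runif(n_streaks, 0.6, 2.5),
                 wpx = runif(n_streaks, 2, 6),
                 shade = sample(c(-0.30, 0.35), n_streaks, replace = TRUE) *
                   runif(n_streaks, 0.7, 1.3))
    })
    sctr <- back_project(pose, cbind(st$u, st$v))
    spc <- t(pose$R %*% (t(cbind(sctr, 0)) - pose$C))
    for (i in seq_len(n_streaks)) {
      cw <- sctr[i, ]
      if (!is.finite(cw[1])) next
      d <- c(sin(st$phi[i]), cos(st$phi[i]))
      hl <- st$len[i] / 2
      ww <- st$wpx[i] * spc[i, 3] / cam$fx
      ends <- rbind(cw + hl * d, cw - hl * d)
      corn <- rbind(ends + rep(ww * 3, 2), ends - rep(ww * 3, 2))
      bb <- project_world(pose, cbind(corn, 0))
      if (anyNA(bb)) next
      c1 <- max(1L, floor(min(bb[, 1]))); c2 <- min(W, ceiling(max(bb[, 1])))
      r1i <- max(1L, floor(min(bb[, 2]))); r2i <- min(H, ceiling(max(bb[, 2])))
      if (c2 < c1 || r2i < r1i) next
      dx <- Xm[r1i:r2i, c1:c2] - cw[1]; dy <- Ym[r1i:r2i, c1:c2] - cw[2]
      along <- dx * d[1] + dy * d[2]
      perp <- -dx * d[2] + dy * d[1]
      wgt <- pmin(pmax((ww - abs(perp)) / (0.35 * ww), 0), 1) *
        pmin(pmax((hl - abs(along)) / (0.25 * hl), 0), 1) *
        grm[r1i:r2i, c1:c2]
      if (!any(wgt > 0)) next
      fac <- 1 + st$shade[i] * wgt
      rm[r1i:r2i, c1:c2] <- clamp01(rm[r1i:r2i, c1:c2] * fac)
      gm[r1i:r2i, c1:c2] <- clamp01(gm[r1i:r2i, c1:c2] * fac)
      bm[r1i:r2i, c1:c2] <- clamp01(bm[r1i:r2i, c1:c2] * fac)
    }
  }

  if (clutter) {
    cl <- withr::with_seed(texture_seed + 4, {
      n <- 8L
      cu <- runif(n, 0.05 * W, 0.95 * W)
      data.frame(u = cu,
                 v = runif(n, 0.03 * H, pmax(line_y(horizon, cu) - 0.05 * H, 0.04 * H)),
                 ru = runif(n, 0.01 * W, 0.04 * W),
                 rv = runif(n, 0.008 * H, 0.02 * H))
    })
    uu <- matrix(u, H, W); vv <- matrix(v, H, W)
    for (i in seq_len(nrow(cl))) {
      m <- ((uu - cl$u[i]) / cl$ru[i])^2 + ((vv - cl$v[i]) / cl$rv[i])^2
      wgt <- pmin(pmax((1 - m) / 0.3, 0), 1) * (!grm)
      rm <- rm * (1 - wgt) + 0.85 * wgt
      gm <- gm * (1 - wgt) + 0.88 * wgt
      bm <- bm * (1 - wgt) + 0.92 * wgt
    }
  }

  # underwater haze: attenuate toward the water color with optical range, so
  # the horizon demarcation is faint (detectable only after adaptive
  # thresholding, as in real reefscapes) and distant texture washes out
  rng <- matrix(sqrt(X^2 + Y^2 + pose$camera_height^2), H, W)
  fog <- exp(-rng / (fog_len * pose$camera_height))
  fog[!grm] <- 1
  depthm <- matrix(v, H, W) / pmax(matrix(line_y(horizon, u), H, W), 2)
  wcr <- 0.10 + 0.06 * depthm; wcg <- 0.24 + 0.10 * depthm; wcb <- 0.42 + 0.12 * depthm
  rm <- rm * fog + wcr * (1 - fog)
  gm <- gm * fog + wcg * (1 - fog)
  bm <- bm * fog + wcb * (1 - fog)

  # backscatter grain: additive path radiance over the substrate, strongest
  # where the resolved texture has faded; unlike scene texture it is not
  # attenuated by the haze, which is what keeps the horizon demarcation
  # detectable after adaptive thresholding
  grain <- matrix(0, H, W)
  grain[gi] <- withr::with_seed(texture_seed + 6, rnorm(length(gi)))
  gsd <- matrix(0, H, W)
  gsd[gi] <- 0.006 + 0.030 * pmin(1, fp / (0.05 / 2))
  rm <- rm + gsd * grain
  gm <- gm + gsd * grain
  bm <- bm + gsd * grain

  marker_px <- NULL
  if (!is.null(markers)) {
    mp <- project_world(pose, cbind(markers$X, markers$Y, 0))
    marker_px <- cbind(markers, x = mp[, 1], y = mp[, 2])
    uu <- matrix(u, H, W); vv <- matrix(v, H, W)
    for (i in seq_len(nrow(marker_px))) {
      if (anyNA(mp[i, ])) next
      d2 <- (uu - mp[i, 1])^2 + (vv - mp[i, 2])^2
      ring <- d2 <= 36; core <- d2 <= 16
      rm[ring] <- 0; gm[ring] <- 0; bm[ring] <- 0
      rm[core] <- 1; gm[core] <- 1; bm[core] <- 1
    }
  }

  img <- array(c(clamp01(rm), clamp01(gm), clamp01(bm)), c(H, W, 3))
  list(img = img,
       truth = list(horizon = horizon, vp = analytic_vp(pose),
                    H_topdown = analytic_topdown(pose),
                    markers = marker_px, pose = pose))
}

#' Render a set of synthetic checkerboard calibration views
#'
#' Seeded poses of a planar checkerboard imaged with the given intrinsics
#' and distortion, for exercising [calibrate_camera()]. 2x2 supersampled.
#'
#' @param cam An `rw_camera` (its `image_size` fixes the render size).
#' @param n_views Number of views (>= 10).
#' @param seed Integer seed.
#' @param rows,cols Inner-corner rows and columns.
#' @param square Square size in world units.
#' @return A list of rasters; each carries the true projected inner corners
#'   as attribute `corners` (row-major), for use as an oracle.
#' @export
render_calibration_set <- function(cam, n_views = 12L, seed = 0L,
                                   rows = 6L, cols = 9L, square = 1) {
  stopifnot(n_views >= 10)
  W <- cam$image_size[1]; H <- cam$image_size[2]
  bw <- (cols + 1) * square; bh <- (rows + 1) * square
  base_d <- cam$fx * bw / (0.62 * W)
  inner <- as.matrix(expand.grid(gx = seq_len(cols), gy = seq_len(rows)))
  inner <- cbind((inner[, 1] - (cols + 1) / 2) * square,
                 (inner[, 2] - (rows + 1) / 2) * square)
  inner <- inner[order(inner[, 2], inner[, 1]), ]
  withr::with_seed(seed, lapply(seq_len(n_views), function(i) {
    for (try in 1:60) {
      rx <- deg2rad(runif(1, -22, 22)); ry <- deg2rad(runif(1, -22, 22))
      rz <- deg2rad(runif(1, -18, 18))
      Rb <- rbind(c(1, 0, 0), c(0, cos(rx), -sin(rx)), c(0, sin(rx), cos(rx))) %*%
        rbind(c(cos(ry), 0, sin(ry)), c(0, 1, 0), c(-sin(ry), 0, cos(ry))) %*%
        rbind(c(cos(rz), -sin(rz), 0), c(sin(rz), cos(rz), 0), c(0, 0, 1))
      tb <- c(runif(1, -0.18, 0.18) * W / cam$fx * base_d,
              runif(1, -0.18, 0.18) * H / cam$fy * base_d,
              base_d * runif(1, 0.85, 1.35))
      pc <- t(Rb %*% t(cbind(inner, 0))) + rep(tb, each = nrow(inner))
      px <- normalized_to_pixel(distort_normalized(
        cbind(pc[, 1] / pc[, 3], pc[, 2] / pc[, 3]), cam), cam)
      if (all(pc[, 3] > 0.2) && all(px[, 1] > 20 & px[, 1] < W - 20 &
                                    px[, 2] > 20 & px[, 2] < H - 20)) break
    }
    img <- render_board(cam, Rb, tb, bw, bh, square)
    attr(img, "corners") <- px
    img
  }))
}

render_board <- function(cam, Rb, tb, bw, bh, square) {
  W <- cam$image_size[1]; H <- cam$image_size[2]
  ss <- c(-0.25, 0.25)
  acc <- 0
  for (du in ss) for (dv in ss) {
    u <- rep(seq_len(W) + du, each = H); v <- rep(seq_len(H) + dv, times = W)
    xy <- pixel_to_normalized(cbind(u, v), cam)
    if (any(c(cam$k1, cam$k2, cam$k3, cam$p1, cam$p2) != 0))
      xy <- undistort_normalized(xy, cam)
    d <- rbind(xy[, 1], xy[, 2], 1)
    n <- Rb[, 3]
    tt <- as.numeric(n %*% tb) / as.numeric(n %*% d)
    pb <- t(Rb) %*% (d * rep(tt, each = 3) - tb)
    bx <- pb[1, ]; by <- pb[2, ]
    on_board <- tt > 0 & abs(bx) <= bw / 2 & abs(by) <= bh / 2
    ix <- floor(bx / square + bw / (2 * square))
    iy <- floor(by / square + bh / (2 * square))
    shade <- ifelse(on_board, ifelse((ix + iy) %% 2 == 0, 0.95, 0.08),
                    0.72 + 0.1 * v / H)
    acc <- acc + shade
  }
  matrix(acc / 4, H, W)
}
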