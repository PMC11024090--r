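# Camera-lens calibration from checkerboard views: saddle-point corner
# detection, planar-homography initialization of the pinhole intrinsics
# (Zhang's method), and Levenberg-Marquardt bundle refinement of the
# intrinsics plus the 5-coefficient Brown distortion model. Underwater use
# folds the housing/water refraction into the calibrated effective focal
# length, so a single in-situ calibration per lens suffices.

#' Construct a camera model
#'
#' Pinhole intrinsics plus Brown radial (`k1, k2, k3`) and tangential
#' (`p1, p2`) distortion coefficients.
#'
#' @param fx,fy Focal lengths in pixels.
#' @param cx,cy Principal point in pixels.
#' @param k1,k2,k3,p1,p2 Distortion coefficients (dimensionless).
#' @param image_size `c(width, height)` at calibration resolution.
#' @param camera_name Lens-model identifier.
#' @param rms_reprojection RMS reprojection error in pixels.
#' @return A list of class `rw_camera`.
#' @export
camera_model <- function(fx, fy, cx, cy, k1 = 0, k2 = 0, k3 = 0, p1 = 0, p2 = 0,
                         image_size = c(NA, NA), camera_name = "unknown",
                         rms_reprojection = NA_real_) {
  stopifnot(fx > 0, fy > 0)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy, k1 = k1, k2 = k2, k3 = k3,
                 p1 = p1, p2 = p2, image_size = image_size,
                 camera_name = camera_name, rms_reprojection = rms_reprojection),
            class = "rw_camera")
}

#' @export
print.rw_camera <- function(x, ...) {
  cat(sprintf("camera '%s': f = (%.1f, %.1f) px, c = (%.1f, %.1f), k = (%.4f, %.4f, %.4f), p = (%.5f, %.5f), rms %.3f px\n",
              x$camera_name, x$fx, x$fy, x$cx, x$cy, x$k1, x$k2, x$k3,
              x$p1, x$p2, x$rms_reprojection))
  invisible(x)
}

#' Write / read a camera model as JSON
#' @param cam An `rw_camera`.
#' @param path JSON file path.
#' @return `path` / an `rw_camera`.
#' @export
write_camera_model <- function(cam, path) {
  jsonlite::write_json(unclass(cam), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_camera_model
#' @export
read_camera_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(camera_model, j[c("fx", "fy", "cx", "cy", "k1", "k2", "k3", "p1", "p2",
                            "image_size", "camera_name", "rms_reprojection")])
}

# Forward Brown distortion of normalized coordinates (n x 2).
distort_normalized <- function(xy, cam) {
  x <- xy[, 1]; y <- xy[, 2]
  r2 <- x^2 + y^2
  rad <- 1 + cam$k1 * r2 + cam$k2 * r2^2 + cam$k3 * r2^3
  xd <- x * rad + 2 * cam$p1 * x * y + cam$p2 * (r2 + 2 * x^2)
  yd <- y * rad + cam$p1 * (r2 + 2 * y^2) + 2 * cam$p2 * x * y
  cbind(xd, yd)
}

# Inverse distortion by fixed-point iteration (distorted -> undistorted).
undistort_normalized <- function(xy, cam, iters = 12L) {
  x <- xy[, 1]; y <- xy[, 2]
  xu <- x; yu <- y
  for (i in seq_len(iters)) {
    r2 <- xu^2 + yu^2
    rad <- 1 + cam$k1 * r2 + cam$k2 * r2^2 + cam$k3 * r2^3
    dx <- 2 * cam$p1 * xu * yu + cam$p2 * (r2 + 2 * xu^2)
    dy <- cam$p1 * (r2 + 2 * yu^2) + 2 * cam$p2 * xu * yu
    xu <- (x - dx) / rad
    yu <- (y - dy) / rad
  }
  cbind(xu, yu)
}

pixel_to_normalized <- function(pts, cam) {
  cbind((pts[, 1] - cam$cx) / cam$fx, (pts[, 2] - cam$cy) / cam$fy)
}
normalized_to_pixel <- function(xy, cam) {
  cbind(xy[, 1] * cam$fx + cam$cx, xy[, 2] * cam$fy + cam$cy)
}

#' Undistort image points
#' @param pts n x 2 distorted pixel coordinates.
#' @param cam An `rw_camera`.
#' @return n x 2 undistorted pixel coordinates.
#' @export
undistort_points <- function(pts, cam) {
  normalized_to_pixel(undistort_normalized(pixel_to_normalized(pts, cam), cam), cam)
}

#' Distort image points (forward model)
#' @inheritParams undistort_points
#' @export
distort_points <- function(pts, cam) {
  normalized_to_pixel(distort_normalized(pixel_to_normalized(pts, cam), cam), cam)
}

#' Remove lens distortion from an image
#'
#' Free-scaling undistortion: the output camera matrix is chosen so that
#' every source pixel is retained (the undistorted extent of the source
#' frame fills the canvas), then each output pixel is mapped through the
#' forward distortion model to its source location and bilinearly sampled.
#' The returned mask marks pixels with a valid source sample; callers crop
#' to [largest_rect_in_mask()] afterwards.
#'
#' @param img Raster.
#' @param cam An `rw_camera`. If the image dimensions differ from the
#'   calibration resolution, the intrinsics are rescaled proportionally.
#' @return A list with `img` and `mask`.
#' @export
undistort_image <- function(img, cam) {
  H <- nrow(img); W <- ncol(img)
  if (!anyNA(cam$image_size) && (cam$image_size[1] != W || cam$image_size[2] != H)) {
    sx <- W / cam$image_size[1]; sy <- H / cam$image_size[2]
    cam <- camera_model(cam$fx * sx, cam$fy * sy, cam$cx * sx, cam$cy * sy,
                        cam$k1, cam$k2, cam$k3, cam$p1, cam$p2, c(W, H),
                        cam$camera_name, cam$rms_reprojection)
  }
  # undistorted extent of the source border fixes the output camera matrix
  bx <- c(seq(1, W, length.out = 200), seq(1, W, length.out = 200),
          rep(1, 200), rep(W, 200))
  by <- c(rep(1, 200), rep(H, 200), seq(1, H, length.out = 200),
          seq(1, H, length.out = 200))
  und <- undistort_points(cbind(bx, by), cam)
  xr <- range(und[, 1]); yr <- range(und[, 2])
  sx <- (W - 1) / diff(xr); sy <- (H - 1) / diff(yr)
  # output pixel -> undistorted source coordinate -> distort -> sample
  grid_x <- rep(seq_len(W), each = H); grid_y <- rep(seq_len(H), times = W)
  ux <- (grid_x - 1) / sx + xr[1]
  uy <- (grid_y - 1) / sy + yr[1]
  src <- distort_points(cbind(ux, uy), cam)
  remap_bilinear_cpp(as.numeric(img), dim(img), src[, 1], src[, 2], W, H, 0)
}

# ---- checkerboard detection -------------------------------------------------

# Detect the inner corners of a fully visible checkerboard. Returns an
# (rows*cols) x 2 matrix ordered row-major to match the board frame, or NULL.
detect_checkerboard <- function(img, rows, cols) {
  g <- gaussian_blur(to_gray(img), 5L, 1.2)
  d1 <- sobel_gradients(g)
  dxx <- sobel_gradients(d1$gx)$gx
  dyy <- sobel_gradients(d1$gy)$gy
  dxy <- sobel_gradients(d1$gx)$gy
  resp <- dxx * dyy - dxy^2  # strongly negative at checker saddle points
  thr <- 0.1 * min(resp)
  cand <- which(resp < thr)
  if (length(cand) < rows * cols) return(NULL)
  r <- (cand - 1L) %% nrow(g) + 1L
  c <- (cand - 1L) %/% nrow(g) + 1L
  o <- order(resp[cand])
  r <- r[o]; c <- c[o]
  # greedy non-max suppression
  keep_r <- numeric(0); keep_c <- numeric(0)
  for (i in seq_along(r)) {
    if (length(keep_r) && any((keep_r - r[i])^2 + (keep_c - c[i])^2 < 49)) next
    keep_r <- c(keep_r, r[i]); keep_c <- c(keep_c, c[i])
    if (length(keep_r) >= 3 * rows * cols) break
  }
  pts <- cbind(x = keep_c, y = keep_r)
  # keep only saddle points with the X-corner signature: the two diagonals
  # must have strongly opposite intensities (rejects border T-junctions)
  H <- nrow(g); W <- ncol(g)
  diag_contrast <- function(rad) {
    xs <- pmin(pmax(pts[, 1], 1 + rad), W - rad)
    ys <- pmin(pmax(pts[, 2], 1 + rad), H - rad)
    i1 <- g[cbind(ys - rad, xs + rad)] + g[cbind(ys + rad, xs - rad)]
    i2 <- g[cbind(ys - rad, xs - rad)] + g[cbind(ys + rad, xs + rad)]
    abs(i1 - i2)
  }
  dc <- pmax(diag_contrast(3L), diag_contrast(5L))
  pts <- pts[dc > 0.55 * max(dc), , drop = FALSE]
  if (nrow(pts) < rows * cols) return(NULL)
  pts <- subpixel_refine(pts, resp)
  order_checkerboard(pts, rows, cols)
}

# Quadratic sub-pixel refinement of response minima.
subpixel_refine <- function(pts, resp) {
  H <- nrow(resp); W <- ncol(resp)
  for (i in seq_len(nrow(pts))) {
    x <- pts[i, 1]; y <- pts[i, 2]
    if (x < 2 || x > W - 1 || y < 2 || y > H - 1) next
    w <- resp[(y - 1):(y + 1), (x - 1):(x + 1)]
    gx <- (w[2, 3] - w[2, 1]) / 2; gy <- (w[3, 2] - w[1, 2]) / 2
    hxx <- w[2, 3] - 2 * w[2, 2] + w[2, 1]
    hyy <- w[3, 2] - 2 * w[2, 2] + w[1, 2]
    hxy <- (w[3, 3] - w[3, 1] - w[1, 3] + w[1, 1]) / 4
    det <- hxx * hyy - hxy^2
    if (abs(det) < 1e-12) next
    dx <- -(hyy * gx - hxy * gy) / det
    dy <- -(hxx * gy - hxy * gx) / det
    if (abs(dx) <= 1 && abs(dy) <= 1) pts[i, ] <- c(x + dx, y + dy)
  }
  pts
}

# Order candidate corners into the row-major board grid via a 4-corner
# homography and iterative nearest-node assignment. A 180-degree board
# ambiguity is harmless (it is absorbed by the view pose).
order_checkerboard <- function(pts, rows, cols) {
  node_match <- function(Hm, grid) {
    proj <- apply_homography(Hm, grid)
    nbr <- apply_homography(Hm, cbind(grid[, 1] + 1, grid[, 2]))
    spacing <- sqrt(rowSums((nbr - proj)^2))  # local cell size per node
    d2 <- outer(proj[, 1], pts[, 1], "-")^2 + outer(proj[, 2], pts[, 2], "-")^2
    nn <- apply(d2, 1, which.min)
    ok <- d2[cbind(seq_len(nrow(grid)), nn)] < (0.45 * spacing)^2 &
      !duplicated(nn) & !duplicated(nn, fromLast = TRUE)
    list(nn = nn, ok = ok)
  }
  for (dims in list(c(cols, rows), c(rows, cols))) {
    nc <- dims[1]; nr <- dims[2]
    s1 <- pts[, 1] + pts[, 2]; s2 <- pts[, 1] - pts[, 2]
    corners <- rbind(pts[which.min(s1), ], pts[which.max(s2), ],
                     pts[which.max(s1), ], pts[which.min(s2), ])
    Hm <- tryCatch(fit_homography(
      quad(c(0, 0), c(nc - 1, 0), c(nc - 1, nr - 1), c(0, nr - 1)), corners),
      error = function(e) NULL)
    if (is.null(Hm)) next
    grid <- as.matrix(expand.grid(gx = 0:(nc - 1), gy = 0:(nr - 1)))
    for (iter in 1:4) {
      m <- node_match(Hm, grid)
      if (sum(m$ok) < 6) { Hm <- NULL; break }
      Hm2 <- tryCatch(dlt_homography(grid[m$ok, , drop = FALSE],
                                     pts[m$nn[m$ok], , drop = FALSE]),
                      error = function(e) NULL)
      if (is.null(Hm2)) break
      Hm <- Hm2
      if (all(m$ok) && iter >= 2) break
    }
    if (is.null(Hm)) next
    m <- node_match(Hm, grid)
    if (all(m$ok)) {
      ord <- order(grid[, 2], grid[, 1])  # row-major (gy, gx)
      out <- pts[m$nn[ord], , drop = FALSE]
      attr(out, "board") <- grid[ord, , drop = FALSE]
      attr(out, "dims") <- c(nr, nc)
      return(out)
    }
  }
  NULL
}

# Normalized DLT homography from n >= 4 correspondences (internal; used by
# the calibration bundle only).
dlt_homography <- function(src, dst) {
  norm_pts <- function(p) {
    mu <- colMeans(p)
    sc <- sqrt(2) / mean(sqrt(rowSums(sweep(p, 2, mu)^2)))
    T <- rbind(c(sc, 0, -sc * mu[1]), c(0, sc, -sc * mu[2]), c(0, 0, 1))
    list(T = T, p = cbind(sc * (p[, 1] - mu[1]), sc * (p[, 2] - mu[2])))
  }
  ns <- norm_pts(src); nd <- norm_pts(dst)
  n <- nrow(src)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- ns$p[i, 1]; y <- ns$p[i, 2]; xp <- nd$p[i, 1]; yp <- nd$p[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, xp * x, xp * y, xp)
    A[2 * i, ] <- c(0, 0, 0, -x, -y, -1, yp * x, yp * y, yp)
  }
  h <- svd(A)$v[, 9]
  Hn <- matrix(h, 3, 3, byrow = TRUE)
  Hm <- solve(nd$T) %*% Hn %*% ns$T
  Hm / Hm[3, 3]
}

# ---- Zhang initialization ---------------------------------------------------

zhang_intrinsics <- function(Hs) {
  vij <- function(Hm, i, j) {
    h <- function(k) Hm[, k]
    hi <- h(i); hj <- h(j)
    c(hi[1] * hj[1], hi[1] * hj[2] + hi[2] * hj[1], hi[2] * hj[2],
      hi[3] * hj[1] + hi[1] * hj[3], hi[3] * hj[2] + hi[2] * hj[3], hi[3] * hj[3])
  }
  V <- do.call(rbind, lapply(Hs, function(Hm) rbind(vij(Hm, 1, 2),
                                                    vij(Hm, 1, 1) - vij(Hm, 2, 2))))
  b <- svd(V)$v[, 6]
  B11 <- b[1]; B12 <- b[2]; B22 <- b[3]; B13 <- b[4]; B23 <- b[5]; B33 <- b[6]
  cy <- (B12 * B13 - B11 * B23) / (B11 * B22 - B12^2)
  lam <- B33 - (B13^2 + cy * (B12 * B13 - B11 * B23)) / B11
  fx <- sqrt(lam / B11)
  fy <- sqrt(lam * B11 / (B11 * B22 - B12^2))
  cx <- -B13 * fx^2 / lam
  list(fx = fx, fy = fy, cx = cx, cy = cy)
}

rodrigues_to_R <- function(r) {
  th <- sqrt(sum(r^2))
  if (th < 1e-12) return(diag(3))
  k <- r / th
  K <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

R_to_rodrigues <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  th <- acos(min(max(ct, -1), 1))
  if (th < 1e-12) return(c(0, 0, 0))
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(th))
  v * th
}

pose_from_homography <- function(Hm, K) {
  A <- solve(K) %*% Hm
  lam <- 1 / sqrt(sum(A[, 1]^2))
  if (A[3, 3] < 0) lam <- -lam  # board in front of the camera
  r1 <- lam * A[, 1]; r2 <- lam * A[, 2]; t <- lam * A[, 3]
  R0 <- cbind(r1, r2, pracma::cross(r1, r2))
  sv <- svd(R0)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) R <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
  list(R = R, t = t)
}

project_board <- function(board_xy, rvec, tvec, cam) {
  R <- rodrigues_to_R(rvec)
  P <- board_xy %*% t(R[, 1:2])
  P <- sweep(P, 2, -tvec, "-")  # n x 3 camera coordinates
  xy <- cbind(P[, 1] / P[, 3], P[, 2] / P[, 3])
  normalized_to_pixel(distort_normalized(xy, cam), cam)
}

#' Calibrate a camera from checkerboard images
#'
#' Detects the inner corners of a planar checkerboard in each view,
#' initializes the pinhole intrinsics from the per-view plane homographies
#' (Zhang's method), and refines intrinsics, distortion, and all poses by
#' Levenberg-Marquardt minimization of the reprojection error. A lens needs
#' to be calibrated only once; persist the result with
#' [write_camera_model()].
#'
#' @param images List of rasters showing the full pattern from varied angles
#'   and frame positions.
#' @param pattern `c(rows, cols, square_size)`: inner-corner rows and
#'   columns, and the square size in world units.
#' @param camera_name Identifier stored in the model.
#' @param min_views Minimum number of views with a detectable pattern.
#' @return An `rw_camera` with `rms_reprojection` filled in.
#' @export
calibrate_camera <- function(images, pattern = c(6, 9, 1), camera_name = "unknown",
                             min_views = 10L) {
  rows <- pattern[1]; cols <- pattern[2]; sq <- pattern[3]
  if (length(images) < min_views)
    stop_rw("CALIBRATION_MISSING", "calibrate",
            sprintf("insufficient views: %d supplied, %d required", length(images), min_views))
  det <- lapply(images, detect_checkerboard, rows = rows, cols = cols)
  ok <- !vapply(det, is.null, TRUE)
  if (sum(ok) < min_views)
    stop_rw("CALIBRATION_MISSING", "calibrate",
            sprintf("pattern detected in only %d/%d views (%d required)",
                    sum(ok), length(images), min_views))
  det <- det[ok]
  W <- ncol(images[[which(ok)[1]]]); H <- nrow(images[[which(ok)[1]]])
  boards <- lapply(det, function(p) attr(p, "board") * sq)  # per-view board frame
  Hs <- lapply(seq_along(det), function(i) dlt_homography(boards[[i]], det[[i]]))
  init <- zhang_intrinsics(Hs)
  if (!is.finite(init$fx) || !is.finite(init$fy) || init$fx <= 0 || init$fy <= 0)
    init <- list(fx = 1.2 * W, fy = 1.2 * W, cx = W / 2, cy = H / 2)
  K <- rbind(c(init$fx, 0, init$cx), c(0, init$fy, init$cy), c(0, 0, 1))
  poses <- lapply(Hs, pose_from_homography, K = K)
  p0 <- c(init$fx, init$fy, init$cx, init$cy, 0, 0, 0, 0, 0,
          unlist(lapply(poses, function(p) c(R_to_rodrigues(p$R), p$t))))
  obs <- do.call(rbind, det)
  nv <- length(det)
  resid_fun <- function(p) {
    cam <- camera_model(p[1], p[2], p[3], p[4], k1 = p[5], k2 = p[6],
                       p1 = p[7], p2 = p[8], k3 = p[9])
    pred <- do.call(rbind, lapply(seq_len(nv), function(v) {
      q <- p[9 + (v - 1) * 6 + 1:6]
      project_board(boards[[v]], q[1:3], q[4:6], cam)
    }))
    as.numeric(pred - obs)
  }
  fit <- minpack.lm::nls.lm(p0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 120))
  p <- fit$par
  res <- matrix(resid_fun(p), ncol = 2)
  rms <- sqrt(mean(rowSums(res^2)))
  camera_model(p[1], p[2], p[3], p[4], k1 = p[5], k2 = p[6], k3 = p[9],
               p1 = p[7], p2 = p[8], image_size = c(W, H),
               camera_name = camera_name, rms_reprojection = rms)
}
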