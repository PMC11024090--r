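# Brute-force oracles and shared fixtures. Scenes are rendered lazily and
# cached for the duration of the test run.

.scene_cache <- new.env(parent = emptyenv())

cached_scene <- function(pitch = 20, roll = 5, seed = 0, size = c(1000, 750), ...) {
  key <- paste(pitch, roll, seed, paste(size, collapse = "x"), ...)
  if (is.null(.scene_cache[[key]])) {
    pose <- scene_pose(pitch = pitch, roll = roll, size = size)
    .scene_cache[[key]] <- render_reefscape(pose, texture_seed = seed, ...)
  }
  .scene_cache[[key]]
}

# Theil-Sen by literal double-loop enumeration of pairwise slopes.
theil_sen_oracle <- function(x, y) {
  n <- length(x)
  slopes <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (x[j] != x[i]) slopes <- c(slopes, (y[j] - y[i]) / (x[j] - x[i]))
  }
  m <- median(slopes)
  list(slope = m, intercept = median(y - m * x))
}

# Otsu by exhaustive scan of all 255 split points, minimizing the weighted
# intra-class variance directly.
otsu_oracle <- function(density) {
  lev <- pmin(as.integer(density * 255), 255L)
  best_t <- NA; best_icv <- Inf
  for (t in 0:254) {
    a <- lev[lev <= t]; b <- lev[lev > t]
    if (!length(a) || !length(b)) next
    icv <- length(a) * var1(a) + length(b) * var1(b)
    if (icv < best_icv) { best_icv <- icv; best_t <- t }
  }
  best_t
}
var1 <- function(v) if (length(v) < 2) 0 else mean((v - mean(v))^2)

# Largest all-ones rectangle by exhaustive row-span enumeration.
largest_rect_oracle <- function(m) {
  H <- nrow(m); W <- ncol(m)
  best <- 0
  for (r1 in 1:H) {
    colsum <- rep(0L, W)
    for (r2 in r1:H) {
      colsum <- colsum + m[r2, ]
      full <- colsum == (r2 - r1 + 1L)
      runs <- rle(full)
      w <- max(c(0, runs$lengths[runs$values]))
      best <- max(best, w * (r2 - r1 + 1L))
    }
  }
  best
}

# Edge density by naive per-pixel window counting (rate form).
density_oracle <- function(edges, r) {
  H <- nrow(edges); W <- ncol(edges)
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    rs <- max(1, i - r):min(H, i + r)
    cs <- max(1, j - r):min(W, j + r)
    out[i, j] <- sum(edges[rs, cs]) / (length(rs) * length(cs))
  }
  mx <- max(out)
  if (mx > 0) out / mx else out
}

# Draw a straight line segment of given thickness into a binary/RGB canvas.
draw_test_line <- function(img, x1, y1, x2, y2, color = c(1, 1, 0), thickness = 3) {
  reefwarp:::draw_segment(img, x1, y1, x2, y2, color, thickness)
}

blank_rgb <- function(H, W, value = 0.2) array(value, c(H, W, 3))
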