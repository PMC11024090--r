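cfg <- rw_config()

test_that("probabilistic Hough recovers drawn structure and handles empties", {
  m <- matrix(0L, 300, 400)
  for (t in seq(0, 1, length.out = 500)) {
    m[round(250 - t * 115), round(100 + t * 200)] <- 1L
  }
  segs <- detect_line_segments(m, cfg)
  expect_gte(nrow(segs), 1)
  ang <- atan2(segs$y2 - segs$y1, segs$x2 - segs$x1) * 180 / pi
  target <- atan2(-115, 200) * 180 / pi
  expect_true(any(abs((ang - target) %% 180) < 2 | abs((ang - target) %% 180) > 178))
  expect_equal(nrow(detect_line_segments(matrix(0L, 50, 50), cfg)), 0)
})

test_that("synthetic reef texture yields many segments under relaxed settings", {
  sc <- cached_scene(pitch = 20, roll = 5, seed = 0)
  edges <- build_edge_map(sc$img, "standard", cfg)
  hy <- sc$truth$horizon$intercept
  edges[seq_len(nrow(edges)) < hy, ] <- 0L
  segs <- detect_line_segments(edges, cfg)
  expect_gte(nrow(segs), 50)
})

test_that("candidate filtering applies angle, side, sign, and balance rules", {
  mk <- function(x1, y1, x2, y2) data.frame(x1 = x1, y1 = y1, x2 = x2, y2 = y2)
  horizon <- rw_line(0, 100)
  # horizontal segment rejected by the minimum-angle rule
  segs <- rbind(mk(10, 200, 100, 200),          # horizontal, left: reject
                mk(50, 400, 150, 250),          # left, negative slope: keep
                mk(600, 250, 700, 400),         # right, positive slope: keep
                mk(650, 250, 750, 150))         # right, negative slope: reject
  out <- filter_candidate_lines(segs, horizon, width = 800, height = 600, config = cfg)
  expect_equal(nrow(out$left), 1)
  expect_equal(nrow(out$right), 1)
  expect_equal(out$right$x1, 600)
  # unbalanced sides are downsampled reproducibly
  left40 <- do.call(rbind, lapply(1:40, function(i) mk(10 + i, 300 + i, 110 + i, 200 + i)))
  right10 <- do.call(rbind, lapply(1:10, function(i) mk(600 + i, 200 + i, 700 + i, 300 + i)))
  big <- rbind(left40, right10)
  o1 <- filter_candidate_lines(big, horizon, 800, 600, cfg)
  o2 <- filter_candidate_lines(big, horizon, 800, 600, cfg)
  expect_equal(nrow(o1$left), 10)
  expect_equal(nrow(o1$right), 10)
  expect_identical(o1$left, o2$left)
  expect_error(filter_candidate_lines(left40, horizon, 800, 600, cfg), "NO_CANDIDATE|side")
})

test_that("candidate vanishing points sit on the horizon near the centre", {
  horizon <- rw_line(0, 100)
  left <- data.frame(x1 = 100, y1 = 400, x2 = 380, y2 = 120)   # y = -x + 500
  right <- data.frame(x1 = 700, y1 = 400, x2 = 420, y2 = 120)  # y = x - 300
  pts <- candidate_vanishing_points(left, right, horizon, width = 800, height = 600,
                                    config = cfg)
  expect_equal(nrow(pts), 1)
  expect_equal(unname(pts[1, ]), c(400, 100), tolerance = 1e-9)
  par <- data.frame(x1 = 100, y1 = 500, x2 = 380, y2 = 220)
  expect_error(candidate_vanishing_points(par, par + c(300, 0, 300, 0), horizon,
                                          800, 600, cfg), "NO_VANISHING|intersections")
  expect_equal(unname(overall_vanishing_point(pts)), c(400, 100))
  sym <- rbind(c(390, 95), c(410, 105))
  expect_equal(unname(overall_vanishing_point(sym)), c(400, 100))
})

test_that("vanishing-line selection minimizes perpendicular distance and extends", {
  vp <- c(400, 100)
  colinear <- data.frame(x1 = 500, y1 = 200, x2 = 700, y2 = 400)  # passes through vp
  offset <- data.frame(x1 = 520, y1 = 200, x2 = 720, y2 = 400)
  pool <- rbind(offset, colinear)
  sel <- select_vanishing_line(pool, vp, anisotropy_index = 150, config = cfg)
  # selected the collinear one (distance 0), extended to 500 px
  len <- sqrt((sel$x2 - sel$x1)^2 + (sel$y2 - sel$y1)^2)
  expect_equal(len, 500, tolerance = 1e-9)
  expect_equal(c((sel$x1 + sel$x2) / 2, (sel$y1 + sel$y2) / 2), c(600, 300))
  dir_in <- c(200, 200) / sqrt(8e4)
  dir_out <- c(sel$x2 - sel$x1, sel$y2 - sel$y1) / 500
  expect_equal(abs(sum(dir_in * dir_out)), 1, tolerance = 1e-12)
  expect_error(select_vanishing_line(pool, vp, anisotropy_index = 450, config = cfg),
               "NO_CANDIDATE|anisotropy")
  # perpendicular distances agree with the closed form on random cases
  set.seed(8)
  for (i in 1:100) {
    seg <- data.frame(x1 = runif(1, 0, 500), y1 = runif(1, 0, 500),
                      x2 = runif(1, 0, 500), y2 = runif(1, 0, 500))
    p <- runif(2, 0, 500)
    a <- seg$y2 - seg$y1; b <- -(seg$x2 - seg$x1); cc <- -(a * seg$x1 + b * seg$y1)
    expect_equal(reefwarp:::perp_distance(seg, p),
                 abs(a * p[1] + b * p[2] + cc) / sqrt(a^2 + b^2), tolerance = 1e-12)
  }
})

test_that("the perspective grid pairs the vanishing line with a full-width horizontal", {
  vl <- data.frame(x1 = 300, y1 = 520, x2 = 500, y2 = 320)
  g <- build_perspective_grid(vl, width = 900, vp = c(420, 100))
  expect_equal(g$horizontal_line$y1, 420)
  expect_equal(g$horizontal_line$y2, 420)
  expect_equal(c(g$horizontal_line$x1, g$horizontal_line$x2), c(0, 900))
  expect_equal((g$vanishing_line$y1 + g$vanishing_line$y2) / 2, g$horizontal_line$y1)
})
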