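test_that("four-point homography fit reproduces trivial maps", {
  sq <- quad(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(fit_homography(sq, sq), diag(3), tolerance = 1e-10)
  shifted <- quad(c(5, 0), c(6, 0), c(6, 1), c(5, 1))
  expect_equal(fit_homography(sq, shifted),
               matrix(c(1, 0, 5, 0, 1, 0, 0, 0, 1), 3, byrow = TRUE),
               tolerance = 1e-10)
  degen <- quad(c(0, 0), c(1, 1), c(2, 2), c(0, 1))  # three collinear corners
  expect_error(fit_homography(degen, sq), "singular|degenerate")
})

test_that("fitting recovers a constructed homography from mapped corners", {
  set.seed(11)
  for (rep in 1:20) {
    Hs <- diag(3) + matrix(runif(9, -0.1, 0.1), 3)
    Hs[3, 3] <- 1
    sq <- quad(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
    dst <- apply_homography(Hs, sq)
    Hfit <- fit_homography(sq, dst)
    expect_equal(Hfit, Hs / Hs[3, 3], tolerance = 1e-9)
  }
})

test_that("apply_homography divides by the homogeneous scaling factor", {
  expect_equal(apply_homography(diag(3), c(13, 7))[1, ], c(x = 13, y = 7))
  expect_equal(apply_homography(diag(c(2, 2, 1)), c(3, 4))[1, ], c(x = 6, y = 8))
  Hp <- diag(3); Hp[3, 1] <- 0.001
  got <- apply_homography(Hp, c(100, 50))
  lam <- 0.001 * 100 + 1  # hand evaluation of the projective division
  expect_equal(got[1, ], c(x = 100 / lam, y = 50 / lam), tolerance = 1e-12)
  Hinf <- diag(3); Hinf[3, ] <- c(-0.01, 0, 1)
  expect_error(apply_homography(Hinf, c(100, 0)), "infinity")
})

test_that("fit/apply round-trips corners on random non-degenerate quads", {
  set.seed(42)
  worst <- 0
  for (i in 1:1000) {
    src <- quad(c(0, 0), c(100, 0), c(100, 80), c(0, 80)) +
      matrix(runif(8, -15, 15), 4)
    dst <- quad(c(0, 0), c(100, 0), c(100, 80), c(0, 80)) +
      matrix(runif(8, -15, 15), 4)
    Hm <- tryCatch(fit_homography(src, dst), error = function(e) NULL)
    if (is.null(Hm)) next
    err <- max(abs(apply_homography(Hm, src) - dst))
    worst <- max(worst, err)
  }
  expect_lt(worst, 1e-6)
})

test_that("warping by the identity and by a translation behaves as expected", {
  img <- matrix(runif(60 * 80), 60, 80)
  out <- warp_image(img, diag(3), c(80, 60))
  expect_equal(out, img, tolerance = 1e-12)
  Ht <- diag(3); Ht[1, 3] <- 10
  sh <- warp_image(img, Ht, c(80, 60))
  expect_equal(sh[, 11:80], img[, 1:70], tolerance = 1e-12)
  expect_true(all(sh[, 1:10] == 0))
})

test_that("warp then inverse-warp approximately restores a smooth image", {
  x <- outer(seq(0, 1, length.out = 120), seq(0, 1, length.out = 160), function(a, b)
    0.5 + 0.3 * sin(4 * a) * cos(5 * b))
  Hm <- fit_homography(quad(c(0, 0), c(160, 0), c(160, 120), c(0, 120)),
                       quad(c(6, 4), c(150, 8), c(155, 116), c(2, 110)))
  there <- warp_image(x, Hm, c(160, 120))
  back <- warp_image(there, solve(Hm), c(160, 120))
  interior <- abs(back - x)[20:100, 20:140]
  expect_lt(mean(interior), 2 / 255)
})

test_that("destination corners follow the compression-factor construction", {
  dc <- destination_corners(1000, 400, 1)
  expect_equal(unname(dc$C_L), c(0, 400))
  expect_equal(unname(dc$C_R), c(1000, 400))
  dc <- destination_corners(1000, 400, 0.5)
  expect_equal(unname(dc$C_L), c(250, 400))
  expect_equal(unname(dc$C_R), c(750, 400))
  expect_error(destination_corners(10, 10, 0), "compression")
  expect_error(destination_corners(10, 10, 1.2), "compression")
  # symmetry and monotone width for arbitrary factors
  xs <- seq(0.05, 1, by = 0.05)
  d <- vapply(xs, function(x) {
    dc <- destination_corners(640, 480, x)
    expect_equal(unname(dc$C_L["x"] + dc$C_R["x"]), 640)
    unname(dc$C_R["x"] - dc$C_L["x"])
  }, numeric(1))
  expect_equal(d, xs * 640)
  expect_true(all(diff(d) > 0))
})

test_that("Theil-Sen fit matches the pairwise-median enumeration exactly", {
  x <- 1:10
  fit <- theil_sen_fit(x, 2 * x + 1)
  expect_equal(c(fit$slope, fit$intercept), c(2, 1))
  two <- theil_sen_fit(c(0, 4), c(1, 9))
  expect_equal(c(two$slope, two$intercept), c(2, 1))
  # gross outliers do not move the fit
  set.seed(7)
  x <- seq_len(20); y <- 2 * x + 1
  xo <- c(x, runif(6, 0, 20)); yo <- c(y, runif(6, 200, 400))
  fit <- theil_sen_fit(xo, yo)
  expect_equal(c(fit$slope, fit$intercept), c(2, 1), tolerance = 1e-9)
  expect_error(theil_sen_fit(rep(3, 5), 1:5), "vertical")
  for (rep in 1:15) {
    n <- sample(3:50, 1)
    x <- sample(1:30, n, replace = TRUE)
    y <- runif(n, -10, 10)
    if (length(unique(x)) < 2) next
    fit <- theil_sen_fit(x, y)
    orc <- theil_sen_oracle(x, y)
    expect_identical(fit$slope, orc$slope)
    expect_identical(fit$intercept, orc$intercept)
  }
})

test_that("inscribed rectangle after rotation matches known and rasterized solutions", {
  r0 <- largest_inscribed_rect_after_rotation(800, 600, 0)
  expect_equal(c(r0$width, r0$height), c(800, 600))
  r45 <- largest_inscribed_rect_after_rotation(200, 200, 45)
  expect_equal(c(r45$width, r45$height), rep(200 / sqrt(2), 2), tolerance = 1 / 200)
  # rasterized containment oracle at 5 degrees
  w <- 800; h <- 600; th <- 5 * pi / 180
  cr <- largest_inscribed_rect_after_rotation(w, h, 5)
  # every crop corner must lie inside the rotated footprint
  corners <- rbind(c(cr$x0, cr$y0), c(cr$x0 + cr$width, cr$y0),
                   c(cr$x0 + cr$width, cr$y0 + cr$height), c(cr$x0, cr$y0 + cr$height))
  Rb <- reefwarp:::rotation_about(-th, w / 2, h / 2)  # map back to unrotated frame
  back <- apply_homography(Rb, corners)
  expect_true(all(back[, 1] >= -1 & back[, 1] <= w + 1 &
                  back[, 2] >= -1 & back[, 2] <= h + 1))
  # maximality against a rasterized search over axis-aligned crops
  mask <- matrix(0L, h, w)
  ctr <- cbind(rep(seq_len(w), each = h), rep(seq_len(h), times = w))
  bk <- apply_homography(Rb, ctr)
  inside <- bk[, 1] >= 0.5 & bk[, 1] <= w + 0.5 & bk[, 2] >= 0.5 & bk[, 2] <= h + 0.5
  mask[cbind(ctr[, 2], ctr[, 1])] <- as.integer(inside)
  raster_best <- largest_rect_in_mask(mask)
  expect_equal(cr$width * cr$height, raster_best$area, tolerance = 0.01)
})

test_that("largest rectangle in a mask equals the exhaustive enumeration", {
  full <- matrix(1L, 80, 100)
  got <- largest_rect_in_mask(full)
  expect_equal(got$area, 8000)
  top <- full; top[1, ] <- 0L
  got <- largest_rect_in_mask(top)
  expect_equal(unlist(got[c("r1", "r2", "area")]), c(r1 = 2, r2 = 80, area = 79 * 100))
  expect_error(largest_rect_in_mask(matrix(0L, 4, 4)), "no valid")
  set.seed(3)
  for (rep in 1:4) {
    m <- matrix(rbinom(2500, 1, 0.7), 50, 50)
    if (!any(m == 1)) next
    expect_equal(largest_rect_in_mask(m)$area, largest_rect_oracle(m))
  }
})
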