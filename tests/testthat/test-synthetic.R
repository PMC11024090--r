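test_that("zero roll gives a level analytic horizon and seeds reproduce scenes", {
  pose <- scene_pose(pitch = 18, roll = 0, size = c(400, 300))
  expect_equal(reefwarp:::analytic_horizon(pose)$slope, 0, tolerance = 1e-12)
  s1 <- render_reefscape(pose, texture_seed = 7, n_blobs = 120, n_streaks = 30)
  s2 <- render_reefscape(pose, texture_seed = 7, n_blobs = 120, n_streaks = 30)
  expect_identical(s1$img, s2$img)
  expect_error(scene_pose(pitch = -5), "pitch")
  expect_error(render_reefscape(scene_pose(pitch = 40, roll = 0, size = c(400, 300))),
               "off-frame")
})

test_that("the rendered water boundary follows the analytic horizon", {
  pose <- scene_pose(pitch = 20, roll = 6, size = c(500, 380))
  sc <- render_reefscape(pose, texture_seed = 1, fog_len = 1e9)  # no haze: sharp boundary
  hz <- sc$truth$horizon
  for (col in c(30, 150, 250, 350, 470)) {
    wy <- hz$slope * col + hz$intercept
    # blue-dominant water immediately above, not blue-dominant ground below
    above <- sc$img[round(wy) - 2, col, ]
    below <- sc$img[round(wy) + 2, col, ]
    expect_gt(above[3], above[1])
    expect_gt(below[1], below[3])
  }
})

test_that("back-projection inverts projection on the ground plane", {
  pose <- scene_pose(pitch = 25, roll = -4, size = c(640, 480))
  set.seed(3)
  w <- cbind(runif(50, -3, 3), runif(50, 1, 15), 0)
  px <- reefwarp:::project_world(pose, w)
  ok <- !is.na(px[, 1])
  back <- back_project(pose, px[ok, ])
  expect_equal(back, w[ok, 1:2], tolerance = 1e-6, ignore_attr = TRUE)
  # compression factor is the bottom-to-top world width ratio, in (0, 1)
  xcf <- x_cf_truth(pose, rbind(c(1, 200), c(640, 200)), rbind(c(1, 480), c(640, 480)))
  expect_gt(xcf, 0); expect_lt(xcf, 1)
})

test_that("the analytic top-down homography equalizes world-equal marker spans", {
  pose <- scene_pose(pitch = 20, roll = 5, size = c(800, 600))
  mk <- default_markers(pose, y_far = 4)
  sc <- render_reefscape(pose, texture_seed = 2, markers = mk)
  m <- sc$truth$markers
  wpts <- apply_homography(sc$truth$H_topdown, cbind(m$x, m$y))
  xs <- m$set == "x"
  sep <- abs(wpts[xs, 1][c(TRUE, FALSE)] - wpts[xs, 1][c(FALSE, TRUE)])
  expect_lt(sd(sep) / mean(sep), 0.01)
  ys <- m$set == "y"
  seg <- abs(diff(wpts[ys, 2]))
  expect_lt(sd(seg) / mean(seg), 0.01)
})

test_that("calibration renders are seeded and show the injected distortion", {
  cam0 <- camera_model(600, 600, 320.5, 240.5, image_size = c(640, 480))
  a <- render_calibration_set(cam0, 10, seed = 5)
  b <- render_calibration_set(cam0, 10, seed = 5)
  expect_identical(a[[3]], b[[3]])
  # straight rows of corners stay straight without distortion
  line_dev <- function(img) {
    pts <- attr(img, "corners")[1:9, ]  # first board row
    fit <- lm(pts[, 2] ~ pts[, 1])
    max(abs(resid(fit)))
  }
  expect_lt(max(vapply(a, line_dev, 1)), 0.5)
  camk <- camera_model(600, 600, 320.5, 240.5, k1 = -0.2, image_size = c(640, 480))
  d <- render_calibration_set(camk, 10, seed = 5)
  expect_gt(max(vapply(d, line_dev, 1)), 2)
})

test_that("clutter is confined to the water column", {
  pose <- scene_pose(pitch = 20, roll = 0, size = c(500, 380))
  plain <- render_reefscape(pose, texture_seed = 3)
  clut <- render_reefscape(pose, texture_seed = 3, clutter = TRUE)
  hy <- round(plain$truth$horizon$intercept)
  expect_identical(plain$img[(hy + 5):380, , ], clut$img[(hy + 5):380, , ])
  expect_false(identical(plain$img[1:(hy - 5), , ], clut$img[1:(hy - 5), , ]))
})
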