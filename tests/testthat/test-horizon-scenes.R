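# Horizon detection and roll removal on rendered scenes with ground truth.

cfg <- rw_config()

test_that("the horizon is recovered within tight tolerances on rendered scenes", {
  # single-scene unit tolerances are looser than the 20-scene acceptance
  # battery: one draw of the texture lottery
  for (spec in list(c(pitch = 20, roll = 5, seed = 0), c(pitch = 28, roll = -6, seed = 1))) {
    sc <- cached_scene(pitch = spec["pitch"], roll = spec["roll"], seed = spec["seed"])
    h <- detect_horizon(sc$img, cfg)
    expect_lt(abs(h$line$slope - sc$truth$horizon$slope), 0.02)
    expect_lt(abs(h$line$intercept - sc$truth$horizon$intercept), 0.02 * nrow(sc$img))
  }
})

test_that("surface clutter above the horizon does not derail detection", {
  pose <- scene_pose(pitch = 20, roll = 4, size = c(1000, 750))
  sc <- render_reefscape(pose, texture_seed = 2, clutter = TRUE)
  h <- detect_horizon(sc$img, cfg)
  expect_lt(abs(h$line$slope - sc$truth$horizon$slope), 0.02)
  expect_lt(abs(h$line$intercept - sc$truth$horizon$intercept), 0.02 * 750)
})

test_that("a frame with no water column raises the dedicated error", {
  sc <- cached_scene(pitch = 20, roll = 5, seed = 0)
  hy <- round(sc$truth$horizon$intercept + sc$truth$horizon$slope * 500)
  reef_only <- sc$img[(hy + 120):nrow(sc$img), , , drop = FALSE]
  err <- tryCatch(detect_horizon(reef_only, cfg), error = function(e) e)
  expect_s3_class(err, "rw_error")
  expect_equal(err$code, "NO_WATER_COLUMN")
})

test_that("roll removal levels the horizon and updates the intercept consistently", {
  sc <- cached_scene(pitch = 20, roll = 7, seed = 3)
  h <- detect_horizon(sc$img, cfg)
  out <- remove_roll(sc$img, h)
  expect_equal(out$horizon$slope, 0)
  expect_true(all(dim(out$img)[1:2] <= dim(sc$img)[1:2]))
  # re-detection on the rotated image is level
  h2 <- detect_horizon(out$img, cfg)
  expect_lt(abs(h2$line$slope), 0.01)
  # intercept oracle: transform points sampled on the original horizon
  xs <- seq(1, 1000, length.out = 50)
  pts <- cbind(xs, reefwarp:::line_y(h$line, xs))
  tp <- apply_homography(out$rotation, pts)
  tp <- cbind(tp[, 1] - out$crop$x0, tp[, 2] - out$crop$y0)
  expect_lt(abs(mean(tp[, 2]) - out$horizon$intercept), 1)
  # zero-slope input passes through untouched
  lev <- list(line = rw_line(0, 123))
  same <- remove_roll(sc$img, lev)
  expect_identical(same$img, sc$img)
  expect_equal(same$horizon$intercept, 123)
})
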