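cfg <- rw_config()

test_that("grid overlay draws on a copy, clips, and errors when fully outside", {
  plane <- blank_rgb(400, 600)
  grid <- list(vanishing_line = data.frame(x1 = 200, y1 = 350, x2 = 400, y2 = 120),
               horizontal_line = data.frame(x1 = 0, y1 = 235, x2 = 600, y2 = 235))
  out <- overlay_grid(plane, grid, top_row = 0, config = cfg)
  expect_equal(plane, blank_rgb(400, 600))  # original untouched
  mask <- reefwarp:::grid_mask(out, cfg)
  # drawn pixels recovered by the color segmentation
  drawn <- which(out[, , 1] > 0.9 & out[, , 3] < 0.1)
  expect_gt(sum(mask[drawn] == 1) / length(drawn), 0.95)
  out_grid <- list(vanishing_line = data.frame(x1 = 10, y1 = 900, x2 = 60, y2 = 950),
                   horizontal_line = data.frame(x1 = 0, y1 = 950, x2 = 600, y2 = 950))
  expect_error(overlay_grid(plane, out_grid, top_row = 0, config = cfg), "outside")
})

test_that("the measured grid angle matches the drawn geometry", {
  plane <- blank_rgb(400, 600)
  perp <- list(vanishing_line = data.frame(x1 = 300, y1 = 50, x2 = 300, y2 = 350),
               horizontal_line = data.frame(x1 = 50, y1 = 200, x2 = 550, y2 = 200))
  a <- measure_grid_angle(overlay_grid(plane, perp, 0, cfg), cfg)
  expect_equal(as.numeric(a), 90, tolerance = 0.5)
  # two lines at 60 degrees
  g60 <- list(vanishing_line = data.frame(x1 = 300 - 150 / sqrt(3), y1 = 350,
                                          x2 = 300 + 150 / sqrt(3), y2 = 50),
              horizontal_line = data.frame(x1 = 50, y1 = 200, x2 = 550, y2 = 200))
  a60 <- measure_grid_angle(overlay_grid(plane, g60, 0, cfg), cfg)
  expect_equal(as.numeric(a60), 60, tolerance = 1)
  # drawn oblique pair measured after an identity warp
  g45 <- list(vanishing_line = data.frame(x1 = 150, y1 = 330, x2 = 430, y2 = 50),
              horizontal_line = data.frame(x1 = 20, y1 = 190, x2 = 580, y2 = 190))
  drawn <- overlay_grid(plane, g45, 0, cfg)
  warped <- warp_image(drawn, diag(3), c(600, 400))
  expect_equal(as.numeric(measure_grid_angle(warped, cfg)), 45, tolerance = 1)
  expect_error(measure_grid_angle(blank_rgb(50, 50), cfg), "grid lost")
})

test_that("a grid already at ninety degrees halts the search immediately", {
  plane <- blank_rgb(300, 500, value = 0.25)
  grid <- list(vanishing_line = data.frame(x1 = 250, y1 = 30, x2 = 250, y2 = 270),
               horizontal_line = data.frame(x1 = 10, y1 = 150, x2 = 490, y2 = 150))
  pg <- overlay_grid(plane, grid, 0, cfg)
  res <- search_compression_factor(pg, 500, 300, config = cfg)
  expect_true(res$converged)
  # the saved iterate is the first one (one extra step confirms the minimum)
  expect_lte(res$n_iterations, 2)
  expect_equal(res$x_cf, 1 - cfg$search_step)
  expect_equal(res$grid_angle_at_stop, 90, tolerance = cfg$angle_tol)
})

test_that("full transformation is deterministic and enforces the resolution floor", {
  small <- array(runif(600 * 800 * 3), c(600, 800, 3))  # 0.48 MP
  expect_error(transform_reefscape(small, config = cfg), "RESOLUTION|megapixels")
  sc <- cached_scene(pitch = 20, roll = 5, seed = 0)
  r1 <- transform_reefscape(sc$img, config = cfg)
  r2 <- transform_reefscape(sc$img, config = cfg)
  expect_identical(r1$transformed, r2$transformed)
  expect_identical(r1$search$x_cf, r2$search$x_cf)
  expect_true(r1$search$converged)
  expect_equal(r1$search$grid_angle_at_stop, 90, tolerance = cfg$angle_tol + 0.5)
})
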