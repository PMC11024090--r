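test_that("anisotropy is the reciprocal variance of orientations", {
  expect_equal(anisotropy(rep(0.3, 50), cap = 1e6), 1e6)
  expect_equal(anisotropy(rep(c(-pi / 4, pi / 4), 100)), 16 / pi^2, tolerance = 1e-12)
  set.seed(2)
  th <- runif(10000, -pi / 2, pi / 2)
  expect_equal(anisotropy(th), 12 / pi^2, tolerance = 0.05 * 12 / pi^2)
  # direct-variance oracle agreement
  for (rep in 1:5) {
    th <- rnorm(sample(10:10000, 1), sd = 0.4)
    v <- mean((th - mean(th))^2)
    expect_equal(anisotropy(th), 1 / v, tolerance = 1e-12)
  }
  expect_error(anisotropy(0.1), "INSUFFICIENT|samples")
})

test_that("anisotropy profile has the documented extent and normalization", {
  # horizontal edges near the top, randomly oriented texture below
  set.seed(4)
  H <- 240; W <- 300
  gray <- matrix(0.5, H, W)
  for (r in seq(22, 90, by = 8)) gray[r, ] <- 0.9             # horizontal stripes
  blob <- matrix(runif(H * W) < 0.04, H, W)
  gray[121:H, ] <- 0.5 + 0.4 * (blob[121:H, ])                # speckle below
  gray <- gaussian_blur(gray, 5, 1)
  edges <- reefwarp:::canny(gray, 30, 90)
  prof <- anisotropy_profile(edges, gray, horizon_y = 20)
  expect_equal(length(prof$rows), floor(H / 2) - 20 + 1)
  expect_true(all(diff(prof$rows) == 1))
  expect_true(all(prof$values >= 0 & prof$values <= 1))
  expect_equal(range(prof$values), c(0, 1))
  # smoothed curve decreases overall: top of the band is more anisotropic
  sm <- reefwarp:::smooth_ma(prof$values, 21)
  expect_gt(mean(sm[1:20]), mean(sm[(length(sm) - 19):length(sm)]))
})

test_that("index selection finds the lower edge of the steep-derivative run", {
  # synthetic curve: flat plateau, then a linear ramp dropping at rate -4
  # (in normalized coordinates), then a gentle tail. The steep run covers
  # normalized rows 0.40-0.60; the selected index is its lower edge.
  n <- 201
  r <- seq(0, 1, length.out = n)
  a <- ifelse(r < 0.4, 1, ifelse(r < 0.6, 1 - 4 * (r - 0.4), 0.2 - 0.2 * (r - 0.6) / 0.4))
  prof <- list(rows = 100 + seq_len(n) - 1, values = (a - min(a)) / diff(range(a)),
               rows_norm = r)
  sel <- select_anisotropy_index(prof, 5)
  expect_false(sel$fallback)
  got_norm <- (sel$row - prof$rows[1]) / (n - 1)
  # the run end lies at the ramp bottom, displaced at most by the adaptive
  # smoothing window (~n/4) and derivative stencil (~n/16)
  expect_gt(got_norm, 0.55)
  expect_lt(got_norm, 0.82)
  # strictly linear shallow curve: no crossing, flagged fallback
  lin <- list(rows = 1:101, values = seq(1, 0.7, length.out = 101),
              rows_norm = seq(0, 1, length.out = 101))
  sel2 <- select_anisotropy_index(lin, 5)
  expect_true(sel2$fallback)
})

test_that("the source plane spans the full width below the index", {
  img <- array(runif(800 * 1000 * 3), c(800, 1000, 3))
  sp <- define_source_plane(img, 300, horizon_y = 150)
  expect_equal(sp$quad, quad(c(0, 300), c(1000, 300), c(1000, 800), c(0, 800)))
  expect_equal(dim(sp$image)[1], 500)  # crop height H - index
  expect_error(define_source_plane(img, 140, horizon_y = 150), "INSUFFICIENT|index")
})
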