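#' Pipeline configuration
#'
#' All tunable parameters of the transformation pipeline with their defaults.
#' Values supplied via `...` or a YAML file (see [read_config()]) override
#' the defaults.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A named list of class `rw_config`.
#'
#' @details Parameters (units; default):
#' \describe{
#'   \item{blur_size, blur_sigma}{Gaussian pre-blur (px; 5, 2).}
#'   \item{canny_low, canny_high}{Canny thresholds on 8-bit gradient
#'     magnitude (50, 150).}
#'   \item{adaptive_block, adaptive_offset}{Adaptive mean-threshold block
#'     size (px; 51) and offset (2/255).}
#'   \item{density_radius_frac}{Edge-density window radius as a fraction of
#'     the image diagonal (0.04), with floor `density_radius_min` (5 px).}
#'   \item{n_water_samples}{Zero-density pixels sampled for the water-column
#'     line (100).}
#'   \item{zscore_threshold}{Outlier cut on contour y-coordinates (2.5).}
#'   \item{hough_threshold, hough_min_len, hough_max_gap}{Relaxed
#'     probabilistic Hough-line settings (votes 10; length 20 px; gap 5 px).}
#'   \item{angle_min_low, angle_min_high, angle_max}{Logical-angle filter
#'     endpoints (degrees; 10, 25, 80). The minimum angle is interpolated in
#'     the horizon intercept between H/3 (25 deg) and 2H/3 (10 deg).}
#'   \item{vp_band_frac}{Vertical tolerance around the horizon for candidate
#'     vanishing points, as a fraction of image height (0.01).}
#'   \item{vp_x_window}{Central x-window for candidate vanishing points, as
#'     fractions of width (c(0.375, 0.625)).}
#'   \item{min_vline_len}{Minimum drawn vanishing-line length (500 px).}
#'   \item{search_step}{Compression-factor decrement per iteration (0.005).}
#'   \item{angle_tol}{Stopping tolerance on the perspective-grid angle
#'     (degrees; 0.5).}
#'   \item{min_megapixels}{Minimum input resolution (0.75).}
#'   \item{seed}{Seed for all stochastic steps (0).}
#' }
#' @export
rw_config <- function(...) {
  cfg <- list(
    blur_size = 5L, blur_sigma = 2,
    canny_low = 50, canny_high = 150,
    adaptive_block = 51L, adaptive_offset = 2 / 255,
    density_radius_frac = 0.04, density_radius_min = 5L,
    n_water_samples = 100L,
    zscore_threshold = 2.5,
    hough_threshold = 10L, hough_min_len = 20L, hough_max_gap = 5L,
    angle_min_low = 10, angle_min_high = 25, angle_max = 80,
    vp_band_frac = 0.01, vp_x_window = c(0.375, 0.625),
    min_vline_len = 500,
    anisotropy_cap = 1e6,
    smooth_window = 5L,
    grid_color = c(1, 1, 0), grid_thickness = 3L,
    hue_tol = 10 / 180, sat_min = 200 / 255, val_min = 200 / 255,
    search_step = 0.005, angle_tol = 0.5,
    min_megapixels = 0.75,
    seed = 0L,
    debug = FALSE
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  structure(cfg, class = "rw_config")
}

#' Read a configuration YAML file
#' @param path Path to a YAML file whose keys are [rw_config()] fields.
#' @return An `rw_config` list.
#' @export
read_config <- function(path) {
  do.call(rw_config, yaml::read_yaml(path))
}
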