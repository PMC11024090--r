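# Full pipeline composition and the batch front-end.

#' Transform a reefscape image into its top-down view
#'
#' Runs the full pipeline: lens undistortion and crop, horizon detection,
#' roll removal, source-plane detection, perspective-grid detection, grid
#' overlay, and the brute-force compression-factor search. Every stage
#' outcome is recorded in the returned object.
#'
#' @param img RGB raster, or a file path.
#' @param cam A camera model (see [calibrate_camera()]) or `NULL` to skip
#'   undistortion (pre-undistorted input).
#' @param config Pipeline configuration, see [rw_config()].
#' @return A list of class `rw_result` with elements `transformed` (the
#'   top-down raster), `search` (the [search_compression_factor()] result),
#'   `horizon`, `roll` (rotation/crop metadata), `anisotropy_index`,
#'   `plane` (source-plane record), `grid`, `undistort_crop`, and `stages`
#'   (per-stage log).
#' @export
transform_reefscape <- function(img, cam = NULL, config = rw_config()) {
  if (is.character(img)) img <- read_image(img)
  if (is.matrix(img)) img <- array(rep(img, 3), c(dim(img), 3))
  stages <- list()
  log_stage <- function(name, ...) stages[[name]] <<- list(...)

  mp <- prod(dim(img)[1:2]) / 1e6
  if (mp < config$min_megapixels)
    stop_rw("RESOLUTION_TOO_LOW", "load",
            sprintf("%.2f megapixels < %.2f minimum", mp, config$min_megapixels))

  und_crop <- NULL
  if (!is.null(cam)) {
    u <- undistort_image(img, cam)
    cr <- largest_rect_in_mask(u$mask)
    img <- u$img[cr$r1:cr$r2, cr$c1:cr$c2, , drop = FALSE]
    und_crop <- cr
    log_stage("undistort", crop = cr)
  }

  horizon <- detect_horizon(img, config)
  log_stage("horizon", slope = horizon$line$slope, intercept = horizon$line$intercept)

  roll <- remove_roll(img, horizon)
  log_stage("roll", angle_deg = atan(horizon$line$slope) * 180 / pi,
            crop = roll$crop)
  rimg <- roll$img
  H <- nrow(rimg); W <- ncol(rimg)
  hy <- roll$horizon$intercept

  gray <- gaussian_blur(to_gray(rimg), config$blur_size, config$blur_sigma)
  edges_std <- build_edge_map(rimg, "standard", config)
  prof <- anisotropy_profile(edges_std, gray, hy, config$anisotropy_cap)
  sel <- select_anisotropy_index(prof, config$smooth_window)
  plane <- define_source_plane(rimg, sel$row, hy)
  log_stage("source_plane", index = sel$row, fallback = sel$fallback)

  edges_grid <- edges_std
  edges_grid[seq_len(nrow(edges_grid)) < line_y(roll$horizon, 1), ] <- 0L
  segs <- detect_line_segments(edges_grid, config)
  cand <- filter_candidate_lines(segs, roll$horizon, W, H, config)
  vpc <- candidate_vanishing_points(cand$left, cand$right, roll$horizon, W, H, config)
  vp <- overall_vanishing_point(vpc)
  vline <- select_vanishing_line(cand$all, vp, sel$row, config)
  vline <- fit_segment_to_box(vline, W, sel$row + 5, H - 5)
  grid <- build_perspective_grid(vline, W, vp)
  log_stage("grid", vp = vp, n_candidates = nrow(vpc),
            n_left = nrow(cand$left), n_right = nrow(cand$right))

  pw <- ncol(plane$image); ph <- nrow(plane$image)
  plane_grid <- overlay_grid(plane$image, grid, plane$top_row, config)
  search <- search_compression_factor(plane_grid, pw, ph, config = config)
  log_stage("search", x_cf = search$x_cf, angle = search$grid_angle_at_stop,
            iterations = search$n_iterations)

  transformed <- warp_image(plane$image, search$homography, c(pw, ph))
  structure(list(transformed = transformed, search = search, horizon = horizon,
                 roll = roll, anisotropy_index = sel$row, plane = plane,
                 grid = grid, undistort_crop = und_crop, stages = stages,
                 config = config),
            class = "rw_result")
}

#' Map original-image points into the top-down view
#'
#' Applies the same geometric chain the pipeline applied to the image: the
#' undistortion crop, the roll rotation and crop, the source-plane crop, and
#' the final homography.
#'
#' @param result An `rw_result` from [transform_reefscape()].
#' @param pts n x 2 matrix of `(x, y)` points in the input image.
#' @return n x 2 matrix of points in the transformed raster.
#' @export
map_to_topdown <- function(result, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, 1)
  if (!is.null(result$undistort_crop)) {
    pts <- cbind(pts[, 1] - (result$undistort_crop$c1 - 1L),
                 pts[, 2] - (result$undistort_crop$r1 - 1L))
  }
  pts <- apply_homography(result$roll$rotation, pts)
  pts <- cbind(pts[, 1] - result$roll$crop$x0, pts[, 2] - result$roll$crop$y0)
  pts <- cbind(pts[, 1], pts[, 2] - result$plane$top_row)
  apply_homography(result$search$homography, pts)
}

#' @export
print.rw_result <- function(x, ...) {
  cat(sprintf(paste0(
    "top-down transformation\n",
    "  horizon: slope %.4f, intercept %.1f px\n",
    "  anisotropy index: row %d\n",
    "  compression factor: %.3f (grid angle %.2f deg, %d iterations)\n"),
    x$horizon$line$slope, x$horizon$line$intercept, x$anisotropy_index,
    x$search$x_cf, x$search$grid_angle_at_stop, x$search$n_iterations))
  invisible(x)
}

#' Process a folder of reefscape images
#'
#' Each image is processed independently; failures are recorded with a
#' failure code and never abort the batch. Transformed images are written as
#' PNG with a JSON sidecar per image.
#'
#' @param input_dir Folder of input images (PNG/TIFF).
#' @param output_dir Folder for outputs (created if missing).
#' @param config Pipeline configuration.
#' @param cam Optional camera model for undistortion.
#' @param camera_name Optional camera-model name; when given with
#'   `calib_params_dir`, a saved calibration is loaded (and required).
#' @param calib_params_dir Folder holding saved calibration JSON files.
#' @param calib_images_dir Folder of calibration-pattern images; used to
#'   calibrate `camera_name` when no saved parameters exist.
#' @param pattern Calibration pattern spec `c(rows, cols, square_size)`.
#' @param cpu_percent Fraction of available CPUs to use (0-1]; the worker
#'   count is `floor(cpu_percent * CPUs)`, minimum 1.
#' @return A list of class `rw_report`: counts, `process_rate`, and a
#'   per-image `records` data frame.
#' @export
run_batch <- function(input_dir, output_dir, config = rw_config(), cam = NULL,
                      camera_name = NULL, calib_params_dir = NULL,
                      calib_images_dir = NULL, pattern = c(6, 9, 1),
                      cpu_percent = 1) {
  if (!dir.exists(input_dir)) stop("input folder does not exist: ", input_dir)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cam) && !is.null(camera_name)) {
    cam <- resolve_camera(camera_name, calib_params_dir, calib_images_dir, pattern)
  }
  files <- sort(list.files(input_dir, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  n_workers <- max(1L, as.integer(floor(cpu_percent * parallel::detectCores())))
  worker <- function(f) {
    t0 <- Sys.time()
    rec <- tryCatch({
      res <- transform_reefscape(f, cam, config)
      base <- tools::file_path_sans_ext(basename(f))
      write_image(res$transformed, file.path(output_dir, paste0(base, "_topdown.png")))
      sidecar <- list(
        image = basename(f), x_cf = res$search$x_cf,
        homography = as.numeric(t(res$search$homography)),
        grid_angle = res$search$grid_angle_at_stop,
        horizon = list(slope = res$horizon$line$slope,
                       intercept = res$horizon$line$intercept),
        anisotropy_index = res$anisotropy_index,
        seed = config$seed, failure_reason = NULL)
      jsonlite::write_json(sidecar, file.path(output_dir, paste0(base, ".json")),
                           auto_unbox = TRUE, digits = NA, null = "null")
      data.frame(image = basename(f), status = "processed", code = NA_character_,
                 stage = NA_character_, message = NA_character_,
                 seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    }, error = function(e) {
      fl <- classify_failure(if (inherits(e, "rw_error")) e$stage else "load", e)
      data.frame(image = basename(f), status = "failed", code = fl$code,
                 stage = fl$stage, message = fl$message,
                 seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    })
    rec
  }
  recs <- if (n_workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(files, worker, mc.cores = n_workers)
  } else {
    lapply(files, worker)
  }
  records <- do.call(rbind, recs)
  n_input <- length(files)
  n_processed <- sum(records$status == "processed")
  structure(list(n_input = n_input, n_processed = n_processed,
                 n_failed = n_input - n_processed,
                 process_rate = if (n_input) n_processed / n_input else NA_real_,
                 records = records),
            class = "rw_report")
}

#' @export
print.rw_report <- function(x, ...) {
  cat(sprintf("batch: %d input, %d processed, %d failed (process rate %.2f)\n",
              x$n_input, x$n_processed, x$n_failed, x$process_rate))
  if (x$n_failed > 0) {
    f <- x$records[x$records$status == "failed", c("image", "code", "stage")]
    print(f, row.names = FALSE)
  }
  invisible(x)
}

resolve_camera <- function(camera_name, calib_params_dir, calib_images_dir, pattern) {
  if (!is.null(calib_params_dir)) {
    f <- file.path(calib_params_dir, paste0(camera_name, ".json"))
    if (file.exists(f)) return(read_camera_model(f))
  }
  if (is.null(calib_images_dir) || !dir.exists(calib_images_dir))
    stop_rw("CALIBRATION_MISSING", "calibrate",
            paste0("no saved parameters and no calibration images for ", camera_name))
  imgs <- lapply(sort(list.files(calib_images_dir, "\\.(png|tif|tiff)$",
                                 ignore.case = TRUE, full.names = TRUE)), read_image)
  cam <- calibrate_camera(imgs, pattern, camera_name = camera_name)
  if (!is.null(calib_params_dir)) {
    dir.create(calib_params_dir, recursive = TRUE, showWarnings = FALSE)
    write_camera_model(cam, file.path(calib_params_dir, paste0(camera_name, ".json")))
  }
  cam
}
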