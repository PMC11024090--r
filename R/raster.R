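#' @useDynLib reefwarp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median var sd runif
#' @importFrom grDevices rgb2hsv
NULL

# Rasters are plain numeric arrays: H x W matrices (grayscale) or H x W x 3
# arrays (RGB), intensities in [0, 1]. Pixel (row r, col c) has continuous
# coordinates (x = c, y = r), y increasing downward.

#' Read an image file as a numeric raster
#'
#' Supports PNG and TIFF. Images are returned as `H x W` matrices (grayscale)
#' or `H x W x 3` arrays (color) with intensities in `[0, 1]`; any alpha
#' channel is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A numeric raster.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_rw("READ_ERROR", "load", paste0("file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop_rw("READ_ERROR", "load", paste0("unsupported image format: .", ext))
  ), error = function(e) {
    if (inherits(e, "rw_error")) stop(e)
    stop_rw("READ_ERROR", "load", conditionMessage(e))
  })
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3L) img <- img[, , 1:3, drop = FALSE] else img <- img[, , 1]
  }
  img
}

#' Write a raster to a PNG file
#' @param img Numeric raster in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(clamp01(img), path)
  invisible(path)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Convert a raster to grayscale
#'
#' Uses the Rec. 601 luma weights (0.299, 0.587, 0.114).
#' @param img Numeric raster.
#' @return An `H x W` matrix.
#' @export
to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

image_size <- function(img) {
  d <- dim(img)
  c(width = d[2], height = d[1])
}

# Replicate-padded shift of a matrix by (dr, dc); used to build small
# convolutions without copying into a padded buffer.
shift_mat <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(seq_len(H) + dr, 1L), H)
  ci <- pmin(pmax(seq_len(W) + dc, 1L), W)
  m[ri, ci, drop = FALSE]
}

# Separable convolution with a 1-D kernel (odd length), replicate boundary.
conv_sep <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * shift_mat(m, i - 1L - r, 0L)
  m2 <- out
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * shift_mat(m2, 0L, i - 1L - r)
  out
}

gaussian_kernel_1d <- function(size, sigma) {
  r <- (size - 1) / 2
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian blur
#' @param img Grayscale matrix or RGB array.
#' @param size Odd kernel size in pixels.
#' @param sigma Standard deviation in pixels.
#' @return Blurred raster of the same shape.
#' @export
gaussian_blur <- function(img, size = 5L, sigma = 2) {
  if (min(dim(img)[1:2]) < size) stop_rw("READ_ERROR", "edges", "image smaller than blur kernel")
  k <- gaussian_kernel_1d(size, sigma)
  if (is.matrix(img)) return(conv_sep(img, k))
  out <- img
  for (c in seq_len(dim(img)[3])) out[, , c] <- conv_sep(img[, , c], k)
  out
}

# Windowed box sums over a (2r+1)^2 neighbourhood via an integral image.
# Outside-image area contributes zero (no padding bias in the counts).
box_sum <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  S <- matrix(0, H + 1L, W + 1L)
  S[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
  r1 <- pmax(seq_len(H) - r, 1L); r2 <- pmin(seq_len(H) + r, H)
  c1 <- pmax(seq_len(W) - r, 1L); c2 <- pmin(seq_len(W) + r, W)
  S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
}

# Number of in-image pixels in each (2r+1)^2 window (for mean filters).
box_count <- function(H, W, r) {
  nr <- pmin(seq_len(H) + r, H) - pmax(seq_len(H) - r, 1L) + 1L
  nc <- pmin(seq_len(W) + r, W) - pmax(seq_len(W) - r, 1L) + 1L
  outer(nr, nc)
}

# Binary morphology with a (2r+1) square structuring element.
dilate_box <- function(m, r) (box_sum(m, r) > 0) * 1L
erode_box <- function(m, r) (box_sum(m, r) >= (2 * r + 1)^2) * 1L

#' Morphological closing with a square structuring element
#' @param m Binary matrix (0/1).
#' @param r Structuring-element radius; the element is `(2r+1) x (2r+1)`.
#' @return Binary matrix.
#' @export
close_box <- function(m, r = 2L) erode_box(dilate_box(m, r), r)
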