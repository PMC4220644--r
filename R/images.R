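# Internal image containers are plain base R objects:
#   - gray image:      integer matrix, values in [0, levels - 1]
#   - binary pattern:  logical matrix (TRUE = foreground)
#   - RGB image:       integer array [height, width, 3], values in [0, 255]
# Matrices are indexed [row, col] with the origin at the top-left.

assert_binary_pattern <- function(x, arg = "pattern") {
  if (!is.matrix(x) || !is.logical(x) || anyNA(x))
    stop(sprintf("`%s` must be a logical matrix without NAs", arg), call. = FALSE)
  invisible(x)
}

assert_gray_image <- function(x, levels = 256L, arg = "gray") {
  if (!is.matrix(x) || !is.numeric(x) || anyNA(x))
    stop(sprintf("`%s` must be a numeric matrix without NAs", arg), call. = FALSE)
  if (any(x != floor(x)) || min(x) < 0 || max(x) > levels - 1)
    stop(sprintf("`%s` must hold integers in [0, %d]", arg, levels - 1L),
         call. = FALSE)
  invisible(x)
}

assert_rgb_image <- function(x, arg = "rgb") {
  if (!is.array(x) || length(dim(x)) != 3 || dim(x)[3] != 3)
    stop(sprintf("`%s` must be a height x width x 3 array", arg), call. = FALSE)
  if (anyNA(x) || min(x) < 0 || max(x) > 255 || any(x != floor(x)))
    stop(sprintf("`%s` must hold 8-bit integer values in [0, 255]", arg),
         call. = FALSE)
  invisible(x)
}

#' Read an 8-bit RGB image (TIFF or PNG)
#'
#' Returns a `height x width x 3` integer array with values in `[0, 255]`.
#' Alpha channels are dropped; gray-scale input is an error because the
#' analysis starts from the red component of a colour image.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return Integer array `[height, width, 3]`.
#' @export
read_image_rgb <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(raw)) != 3 || dim(raw)[3] < 3)
    stop("expected an RGB image: ", path, call. = FALSE)
  out <- array(as.integer(round(raw[, , 1:3] * 255)), dim = c(dim(raw)[1:2], 3))
  out
}

#' Write a binary mask as an 8-bit PNG (foreground 255, background 0)
#'
#' @param pattern Logical matrix.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(pattern, path) {
  assert_binary_pattern(pattern)
  png::writePNG(matrix(as.numeric(pattern), nrow(pattern)), path)
  invisible(path)
}

#' Write an 8-bit RGB image as TIFF
#'
#' @param rgb Integer array `[height, width, 3]` with values in `[0, 255]`.
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(rgb, path) {
  assert_rgb_image(rgb)
  tiff::writeTIFF(rgb / 255, path, bits.per.sample = 8L)
  invisible(path)
}
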