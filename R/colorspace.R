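#' @title Colour-space conversions and image I/O
#'
#' @description Images are plain R arrays: an RGB image is an `H x W x 3`
#' numeric array with integer intensities in `[0, 255]`; a mask is an
#' `H x W` logical matrix (`TRUE` = lesion / foreground); a label map is an
#' `H x W` integer matrix whose labels form the contiguous range
#' `1..n_labels`.  All conversions are vectorised wrappers around
#' \pkg{farver} (sRGB primaries, D65 reference white for CIE-L*a*b*),
#' except YCbCr which uses the full-range BT.601 matrix.
#'
#' @name colorspace
NULL

assert_rgb_image <- function(img, arg = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(sprintf("`%s` must be an H x W x 3 array", arg), call. = FALSE)
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop(sprintf("`%s` must contain intensities in [0, 255]", arg), call. = FALSE)
  invisible(img)
}

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    stop(sprintf("`%s` must be a logical matrix", arg), call. = FALSE)
  if (anyNA(mask)) stop(sprintf("`%s` must not contain NA", arg), call. = FALSE)
  invisible(mask)
}

assert_same_shape <- function(a, b) {
  if (!identical(dim(a)[1:2], dim(b)[1:2]))
    stop("mask/image shapes differ", call. = FALSE)
  invisible(NULL)
}

#' Build an RGB image array from channel matrices
#' @param r,g,b numeric matrices of identical shape, values in `[0, 255]`.
#' @return an `H x W x 3` RGB array.
#' @export
rgb_image <- function(r, g, b) {
  img <- array(c(r, g, b), dim = c(dim(r), 3L))
  assert_rgb_image(img)
}

convert_channels <- function(img, to) {
  d <- dim(img)
  m <- matrix(as.numeric(img), ncol = 3L)
  out <- farver::convert_colour(m, from = "rgb", to = to)
  array(out, dim = d)
}

#' Convert an RGB image to CIE-L*a*b*
#'
#' sRGB companding, D65 reference white.  `L*` lies in `[0, 100]`; `a*` and
#' `b*` roughly in `[-128, 127]`.
#'
#' @param img `H x W x 3` RGB array with values in `[0, 255]`.
#' @return `H x W x 3` numeric array of (L*, a*, b*) planes.
#' @export
rgb_to_lab <- function(img) {
  assert_rgb_image(img)
  convert_channels(img, "lab")
}

#' Convert CIE-L*a*b* planes back to an RGB image
#' @param lab `H x W x 3` array of (L*, a*, b*).
#' @return RGB array with values clamped to `[0, 255]` and rounded.
#' @export
lab_to_rgb <- function(lab) {
  d <- dim(lab)
  m <- matrix(as.numeric(lab), ncol = 3L)
  out <- farver::convert_colour(m, from = "lab", to = "rgb")
  out <- round(pmin(255, pmax(0, out)))
  array(out, dim = d)
}

#' Convert an RGB image to HSV
#'
#' Standard hexcone model: H in degrees `[0, 360)` (0 for achromatic
#' pixels), S and V in `[0, 1]`.
#'
#' @inheritParams rgb_to_lab
#' @return `H x W x 3` numeric array of (H, S, V) planes.
#' @export
rgb_to_hsv_img <- function(img) {
  assert_rgb_image(img)
  out <- convert_channels(img, "hsv")
  out[, , 1][is.na(out[, , 1])] <- 0
  out[, , 1] <- out[, , 1] %% 360
  out
}

#' Convert an RGB image to YCbCr
#'
#' Full-range (JPEG) BT.601 coefficients; achromatic input maps to
#' Cb = Cr = 128.
#'
#' @inheritParams rgb_to_lab
#' @return `H x W x 3` numeric array of (Y, Cb, Cr) planes.
#' @export
rgb_to_ycbcr <- function(img) {
  assert_rgb_image(img)
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  y  <- 0.299 * r + 0.587 * g + 0.114 * b
  cb <- 128 - 0.168736 * r - 0.331264 * g + 0.5 * b
  cr <- 128 + 0.5 * r - 0.418688 * g - 0.081312 * b
  clamp(array(c(y, cb, cr), dim = dim(img)), 0, 255)
}

#' Luma grayscale plane of an RGB image
#' @inheritParams rgb_to_lab
#' @return `H x W` numeric matrix in `[0, 255]` (BT.601 luma).
#' @export
rgb_to_gray <- function(img) {
  assert_rgb_image(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Read an RGB image (PNG or JPEG)
#' @param path file path; format inferred from the extension.
#' @return `H x W x 3` RGB array with integer values in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  img <- round(px * 255)
  assert_rgb_image(img, "path")
}

#' Write an RGB image as PNG
#' @param img RGB array.
#' @param path output path (PNG).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  assert_rgb_image(img)
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Read a binary mask from a 0/255 PNG
#'
#' Any grey PNG is accepted; pixels at or above 50% intensity are
#' foreground.
#'
#' @param path PNG file path.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  if (!is.matrix(px)) stop("mask must be a 2-D PNG", call. = FALSE)
  px >= 0.5
}

#' Write a binary mask as a 0/255 PNG
#' @param mask logical matrix.
#' @param path output path (PNG).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
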