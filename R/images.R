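# Image containers are plain base-R objects: a grayscale image is an H x W
# numeric matrix of integers in [0, 255]; an RGB image is an H x W x 3 array.
# Rows are the tangential direction, columns the radial (pith -> bark) axis.

is_rgb_image <- function(img) is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L

is_gray_image <- function(img) is.matrix(img) && is.numeric(img)

check_image <- function(img, arg = "img") {
  if (!is_rgb_image(img) && !is_gray_image(img))
    stop(sprintf("'%s' must be an H x W numeric matrix or an H x W x 3 array", arg))
  if (length(img) == 0L || any(dim(img)[1:2] == 0L))
    stop(sprintf("'%s' is empty", arg))
  rng <- range(img)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    stop(sprintf("'%s' must contain finite values in [0, 255]", arg))
  invisible(img)
}

#' Read a micrograph image
#'
#' Reads an 8-bit PNG, TIFF or JPEG image of a wood cross-section and returns
#' it as an integer-valued array on the 0--255 scale: an H x W matrix for
#' grayscale input, an H x W x 3 array for colour input (an alpha channel,
#' if present, is dropped).
#'
#' @param path Path to a `.png`, `.tif(f)`, `.jpg` or `.jpeg` file.
#' @return Numeric matrix (grayscale) or H x W x 3 array (RGB), values in
#'   `[0, 255]`.
#' @export
read_micrograph <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG requires the 'jpeg' package")
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: .", ext)
  )
  if (is.array(raw) && length(dim(raw)) == 3L) {
    if (dim(raw)[3] >= 3L) raw <- raw[, , 1:3, drop = FALSE]
    else raw <- raw[, , 1L]           # gray + alpha
  }
  img <- round(raw * 255)
  check_image(img, "image file")
  img
}

#' Write a binary wall/void mask as an 8-bit PNG
#'
#' Void pixels are written white (255), wall pixels black (0), matching the
#' binarized-image convention of the pipeline.
#'
#' @param mask Logical matrix, `TRUE` = void (see [binarize()]).
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.matrix(mask), is.logical(mask))
  png::writePNG(ifelse(mask, 1, 0), target = path)
  invisible(path)
}

#' Write a grayscale or RGB image as an 8-bit PNG
#'
#' @param img Image on the 0--255 scale (matrix or H x W x 3 array).
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  check_image(img)
  png::writePNG(img / 255, target = path)
  invisible(path)
}

#' Read a binary mask written by [write_mask_png()]
#'
#' @param path Path to an 8-bit PNG mask (0 = wall, 255 = void).
#' @return Logical matrix, `TRUE` = void.
#' @export
read_mask_png <- function(path) {
  img <- read_micrograph(path)
  if (is_rgb_image(img)) img <- to_grayscale(img)
  img > 127
}
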