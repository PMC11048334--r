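# Preprocessing chain: Gaussian smoothing -> grayscale -> gray-level
# histogram -> Otsu threshold -> binary wall/void mask.

# Separable Gaussian convolution of a numeric matrix, unrounded.
# Kernel radius ceiling(3*sigma); borders handled by mirror reflection
# (edge row/column not repeated), so a constant image is exactly preserved.
smooth_matrix <- function(m, sigma) {
  r <- as.integer(ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  H <- nrow(m); W <- ncol(m)
  if (H <= r || W <= r)
    stop(sprintf("image too small for sigma = %g (kernel radius %d)", sigma, r))
  refl <- function(n) c(rev(seq_len(r)) + 1L, seq_len(n), n - seq_len(r))
  mp <- m[refl(H), , drop = FALSE]
  out <- matrix(0, H, W)
  for (i in seq_along(k)) out <- out + k[i] * mp[(i - 1L) + seq_len(H), , drop = FALSE]
  mp <- out[, refl(W), drop = FALSE]
  out <- matrix(0, H, W)
  for (i in seq_along(k)) out <- out + k[i] * mp[, (i - 1L) + seq_len(W), drop = FALSE]
  out
}

#' Gaussian smoothing of a micrograph
#'
#' Convolves the image with a normalized Gaussian kernel of standard
#' deviation `sigma` pixels (radius `ceiling(3*sigma)`), each colour channel
#' independently. Borders are handled by mirror reflection; output values are
#' rounded back to integers and clamped to `[0, 255]`.
#'
#' Smoothing suppresses pixel noise ahead of binarization, giving clearer
#' cell-wall contours; it is the first step of [preprocess()].
#'
#' @param img Grayscale matrix or RGB array on the 0--255 scale.
#' @param sigma Kernel standard deviation in pixels; must be positive.
#' @return Smoothed image of the same shape and scale.
#' @export
gaussian_smooth <- function(img, sigma = 2) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a single positive number")
  check_image(img)
  clamp <- function(m) pmin(pmax(round(m), 0), 255)
  if (is_rgb_image(img)) {
    out <- img
    for (ch in 1:3) out[, , ch] <- clamp(smooth_matrix(img[, , ch], sigma))
    out
  } else {
    clamp(smooth_matrix(img, sigma))
  }
}

#' Convert an RGB micrograph to grayscale
#'
#' Uses the fixed ITU-R BT.601 luma weights 0.299 R + 0.587 G + 0.114 B,
#' rounded to the nearest integer, so that conversion is reproducible across
#' runs and machines.
#'
#' @param img H x W x 3 array on the 0--255 scale (a grayscale matrix is
#'   returned unchanged).
#' @return H x W integer-valued matrix in `[0, 255]`.
#' @export
to_grayscale <- function(img) {
  check_image(img)
  if (is_gray_image(img)) return(img)
  round(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
}

#' Gray-level histogram of an image
#'
#' Tallies pixels into the 256 gray levels 0..255. The histogram is the input
#' to [otsu_threshold()]; in stained wood sections it is typically bimodal,
#' with one mode for dark cell walls and one for light voids.
#'
#' @param img Grayscale matrix with integer values in `[0, 255]`.
#' @return Object of class `gray_histogram`: list with `counts` (256 integers)
#'   and `total` (pixel count).
#' @export
gray_histogram <- function(img) {
  check_image(img)
  if (!is_gray_image(img)) stop("'img' must be a grayscale matrix; see to_grayscale()")
  if (any(img != round(img))) stop("grayscale values must be integers in [0, 255]")
  counts <- tabulate(as.integer(img) + 1L, nbins = 256L)
  structure(list(counts = counts, total = length(img)), class = "gray_histogram")
}

#' @export
print.gray_histogram <- function(x, ...) {
  nz <- which(x$counts > 0L) - 1L
  cat(sprintf("Gray-level histogram: %d pixels, %d populated levels (range %d-%d)\n",
              x$total, length(nz), min(nz), max(nz)))
  invisible(x)
}

as_gray_histogram <- function(x) {
  if (inherits(x, "gray_histogram")) return(x)
  if (is_gray_image(x)) return(gray_histogram(x))
  if (is.numeric(x) && length(x) == 256L && all(x >= 0) && all(x == round(x)))
    return(structure(list(counts = as.integer(x), total = sum(x)),
                     class = "gray_histogram"))
  stop("expected a gray_histogram, a grayscale matrix, or 256 non-negative counts")
}

#' Otsu's threshold
#'
#' Finds the gray level `t` in `[0, 254]` that splits the histogram into a
#' dark class (levels <= t) and a light class (levels > t) minimizing the
#' intra-class variance
#' \deqn{\sigma_\omega^2(t) = \omega_1 \sigma_1^2 + \omega_2 \sigma_2^2,}
#' where \eqn{\omega_1, \omega_2} are the class shares and
#' \eqn{\sigma_1, \sigma_2} the class standard deviations (equivalently,
#' maximizing the between-class variance). Only splits with both classes
#' non-empty are considered; ties are broken by the smallest threshold so the
#' result is deterministic.
#'
#' @param x A `gray_histogram`, a grayscale matrix, or a vector of 256 counts.
#' @return Integer threshold in `[0, 254]`.
#' @export
otsu_threshold <- function(x) {
  h <- as_gray_histogram(x)
  counts <- as.numeric(h$counts)
  if (sum(counts > 0) < 2L)
    stop("degenerate histogram: need at least two populated gray levels")
  lev <- 0:255
  W1 <- cumsum(counts)
  S1 <- cumsum(counts * lev)
  Q1 <- cumsum(counts * lev^2)
  Tn <- W1[256]; ST <- S1[256]; QT <- Q1[256]
  i <- 1:255                       # candidate thresholds t = 0..254
  w1 <- W1[i]; w2 <- Tn - w1
  valid <- w1 > 0 & w2 > 0
  ss1 <- Q1[i] - S1[i]^2 / w1
  ss2 <- (QT - Q1[i]) - (ST - S1[i])^2 / w2
  within <- (ss1 + ss2) / Tn
  within[!valid] <- Inf
  m <- min(within)
  tol <- 1e-9 * (1 + abs(m))
  as.integer(which(within <= m + tol)[1L] - 1L)
}

#' Binarize a grayscale image at a threshold
#'
#' Classifies every pixel as void (light class, gray value > `threshold`) or
#' wall (dark class, value <= `threshold`). For sections where walls stain
#' lighter than the voids, `invert = TRUE` flips the polarity.
#'
#' @param img Grayscale matrix on the 0--255 scale.
#' @param threshold Integer in `[0, 254]`, e.g. from [otsu_threshold()].
#' @param invert If `TRUE`, the dark class becomes void.
#' @return Logical matrix (`TRUE` = void) with attribute `threshold`.
#' @export
binarize <- function(img, threshold, invert = FALSE) {
  check_image(img)
  if (!is_gray_image(img)) stop("'img' must be a grayscale matrix")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold != round(threshold) || threshold < 0 || threshold > 254)
    stop("'threshold' must be a single integer in [0, 254]")
  mask <- if (invert) img <= threshold else img > threshold
  attr(mask, "threshold") <- as.integer(threshold)
  mask
}

#' Full binarization chain for a micrograph
#'
#' Applies the two-step transformation used throughout the package: Gaussian
#' smoothing (per channel), grayscale conversion, Otsu threshold on the
#' gray-level histogram, and binarization into a wall/void mask. The chosen
#' threshold is reported via `message()` and stored on the result.
#'
#' @param img RGB array or grayscale matrix on the 0--255 scale.
#' @param sigma Gaussian smoothing standard deviation in pixels; `sigma = 0`
#'   skips smoothing.
#' @param invert Flip wall/void polarity (see [binarize()]).
#' @param quiet Suppress the threshold message.
#' @return Logical mask (`TRUE` = void) with attributes `threshold` and `sigma`.
#' @export
preprocess <- function(img, sigma = 2, invert = FALSE, quiet = FALSE) {
  check_image(img)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma < 0)
    stop("'sigma' must be a single non-negative number")
  if (sigma > 0) img <- gaussian_smooth(img, sigma)
  gray <- to_grayscale(img)
  t <- otsu_threshold(gray_histogram(gray))
  if (!quiet) message("Otsu threshold: ", t)
  mask <- binarize(gray, t, invert = invert)
  attr(mask, "sigma") <- sigma
  mask
}
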