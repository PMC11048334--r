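# The virtual sensor: a one-pixel-thick scanning line of fixed tangential
# length advances along the radial (column) axis of a binary mask and records
# the void fraction of each column segment. Several overlapping tangential
# windows give replicate porosity profiles that are averaged pixelwise.
#
# Conventions: pixel coordinates are 0-based; radial intervals are half-open
# [start, end); a profile value at index k covers radial pixel origin + k - 1
# in R's 1-based vectors.

#' Lay out overlapping tangential scan areas
#'
#' Places windows of `window` rows at tangential offsets `0, step, 2*step, ...`
#' as long as they fit within the image. With the defaults (1000-pixel window,
#' 200-pixel step) an 1800-pixel-tall image yields five scan areas, so every
#' ring is measured five times. If the image is shorter than `window`, a
#' single full-height area is returned with a warning.
#'
#' @param image_height Image height in pixels (tangential extent).
#' @param window Scan-line length (window height) in pixels.
#' @param step Tangential shift between consecutive windows, in pixels.
#' @return `data.frame` with columns `offset` (0-based top row) and `height`.
#' @export
make_scan_areas <- function(image_height, window = 1000L, step = 200L) {
  stopifnot(length(image_height) == 1L, image_height >= 1)
  if (!is.numeric(window) || length(window) != 1L || window < 1)
    stop("'window' must be a positive number of pixels")
  if (!is.numeric(step) || length(step) != 1L || step < 1)
    stop("'step' must be a positive number of pixels")
  window <- as.integer(window); step <- as.integer(step)
  if (image_height < window) {
    warning(sprintf(
      "image height %d < window %d; using a single full-height scan area",
      as.integer(image_height), window))
    return(data.frame(offset = 0L, height = as.integer(image_height)))
  }
  offsets <- seq.int(0L, as.integer(image_height) - window, by = step)
  data.frame(offset = offsets, height = window)
}

check_area <- function(mask, area) {
  if (is.numeric(area) && length(area) == 2L)
    area <- list(offset = area[1], height = area[2])
  offset <- as.integer(area$offset); height <- as.integer(area$height)
  if (is.na(offset) || is.na(height) || offset < 0 || height < 1 ||
      offset + height > nrow(mask))
    stop(sprintf("scan area [%s, %s) outside image of height %d",
                 area$offset, area$offset + area$height, nrow(mask)))
  list(offset = offset, height = height)
}

check_radial_range <- function(mask, radial_range) {
  if (is.null(radial_range)) return(c(0L, ncol(mask)))
  rr <- as.integer(radial_range)
  if (length(rr) != 2L || any(is.na(rr)) || rr[1] < 0 || rr[2] <= rr[1] ||
      rr[2] > ncol(mask))
    stop(sprintf("radial range [%s, %s) outside image of width %d",
                 radial_range[1], radial_range[2], ncol(mask)))
  rr
}

#' Scan one porosity profile within a tangential window
#'
#' For every radial pixel in `radial_range`, counts the void pixels on the
#' one-pixel-thick scanning line spanning the window rows and divides by the
#' window height, yielding the porosity (void fraction) at that radial
#' position.
#'
#' @param mask Logical wall/void mask (`TRUE` = void), e.g. from
#'   [preprocess()].
#' @param area Scan area: a row of [make_scan_areas()] output, a
#'   `list(offset=, height=)`, or a numeric `c(offset, height)` (0-based
#'   offset).
#' @param radial_range Half-open 0-based pixel interval `c(start, end)` along
#'   the radial axis; `NULL` scans the full width.
#' @return Numeric vector of porosities in `[0, 1]` with attributes `origin`
#'   (0-based radial pixel of the first value) and `scan_area`.
#' @export
scan_profile <- function(mask, area, radial_range = NULL) {
  stopifnot(is.matrix(mask), is.logical(mask))
  a <- check_area(mask, area)
  rr <- check_radial_range(mask, radial_range)
  rows <- a$offset + seq_len(a$height)
  cols <- (rr[1] + 1L):rr[2]
  values <- colSums(mask[rows, cols, drop = FALSE]) / a$height
  structure(values, origin = rr[1], scan_area = c(offset = a$offset, height = a$height))
}

#' Porosity profiles over all scan areas, plus their average
#'
#' Runs the virtual sensor once per scan area from [make_scan_areas()] and
#' forms the averaged profile as the pixelwise arithmetic mean across areas.
#' Per-ring statistics downstream are computed on this averaged profile.
#'
#' @inheritParams scan_profile
#' @inheritParams make_scan_areas
#' @return Object of class `profile_set`: list with `profiles` (length x
#'   n_areas matrix, one column per scan area), `averaged` (numeric vector),
#'   `areas` (the layout data frame) and `origin`.
#' @export
profile_set <- function(mask, window = 1000L, step = 200L, radial_range = NULL) {
  stopifnot(is.matrix(mask), is.logical(mask))
  areas <- make_scan_areas(nrow(mask), window, step)
  rr <- check_radial_range(mask, radial_range)
  prof <- vapply(seq_len(nrow(areas)),
                 function(i) as.numeric(scan_profile(mask, areas[i, ], rr)),
                 numeric(rr[2] - rr[1]))
  prof <- matrix(prof, nrow = rr[2] - rr[1], ncol = nrow(areas),
                 dimnames = list(NULL, paste0("area", seq_len(nrow(areas)))))
  structure(list(profiles = prof, averaged = rowMeans(prof),
                 areas = areas, origin = rr[1]),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf("Porosity profile set: %d scan areas (window %d px), %d radial px from pixel %d\n",
              ncol(x$profiles), x$areas$height[1], nrow(x$profiles), x$origin))
  cat(sprintf("  averaged porosity: mean %.3f, range [%.3f, %.3f]\n",
              mean(x$averaged), min(x$averaged), max(x$averaged)))
  invisible(x)
}

#' Correlation of each scan-area profile with the averaged profile
#'
#' Pearson correlation between every per-window porosity profile and the
#' pixelwise averaged profile; high values indicate that the tangential
#' windows carry a common radial signal rather than local disturbances
#' (rays, large vessels, preparation defects). A zero-variance profile yields
#' `NA` with a warning rather than an arbitrary number.
#'
#' @param pset A `profile_set` from [profile_set()].
#' @return `data.frame` with columns `area`, `offset`, `n` and `r`.
#' @export
profile_correlation_table <- function(pset) {
  stopifnot(inherits(pset, "profile_set"))
  if (nrow(pset$profiles) < 3L) stop("profiles must have length >= 3")
  avg <- pset$averaged
  r <- vapply(seq_len(ncol(pset$profiles)), function(i) {
    v <- pset$profiles[, i]
    if (stats::sd(v) == 0 || stats::sd(avg) == 0) {
      warning(sprintf("scan area %d: zero-variance profile, correlation undefined", i))
      return(NA_real_)
    }
    cor(v, avg)
  }, numeric(1))
  data.frame(area = seq_len(ncol(pset$profiles)),
             offset = pset$areas$offset,
             n = nrow(pset$profiles),
             r = r)
}

#' Write a profile set to CSV
#'
#' One row per radial pixel: `radial_pixel` (0-based), one `por_areaN` column
#' per scan area, and `por_mean` for the averaged profile.
#'
#' @param pset A `profile_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(pset, path) {
  stopifnot(inherits(pset, "profile_set"))
  df <- data.frame(radial_pixel = pset$origin + seq_len(nrow(pset$profiles)) - 1L)
  for (i in seq_len(ncol(pset$profiles))) df[[paste0("por_area", i)]] <- pset$profiles[, i]
  df$por_mean <- pset$averaged
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
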