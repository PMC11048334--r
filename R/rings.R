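# Ring annotations combine with averaged porosity profiles into per-ring
# statistics (width, max/mean/min porosity) and per-specimen annual series.

#' Read a ring-boundary annotation table
#'
#' Expected CSV schema: `specimen_id, year, image, start_px, end_px`, one row
#' per growth ring, where `[start_px, end_px)` is the ring's half-open 0-based
#' radial pixel interval in the named image. Annotations are validated with
#' [validate_ring_annotations()].
#'
#' @param path CSV file path.
#' @return Validated annotation `data.frame`.
#' @export
read_ring_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_ring_annotations(df)
}

#' Validate ring annotations
#'
#' Enforces the annotation invariants: required columns present; `end_px >
#' start_px`; within each specimen no duplicate years, no overlapping
#' intervals, and years strictly increasing with radial position (rings
#' accumulate outward from the pith).
#'
#' @param df Annotation `data.frame` (see [read_ring_annotations()]).
#' @return `df`, ordered by specimen and radial position.
#' @export
validate_ring_annotations <- function(df) {
  need <- c("specimen_id", "year", "image", "start_px", "end_px")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("annotation table is empty")
  if (any(df$end_px <= df$start_px))
    stop("annotations with end_px <= start_px: rows ",
         paste(which(df$end_px <= df$start_px), collapse = ", "))
  df <- df[order(df$specimen_id, df$start_px), , drop = FALSE]
  for (sp in unique(df$specimen_id)) {
    d <- df[df$specimen_id == sp, , drop = FALSE]
    dup <- d$year[duplicated(d$year)]
    if (length(dup))
      stop(sprintf("specimen '%s': duplicate year(s) %s", sp, paste(unique(dup), collapse = ", ")))
    if (nrow(d) > 1L) {
      ov <- which(d$start_px[-1L] < d$end_px[-nrow(d)])
      if (length(ov))
        stop(sprintf("specimen '%s': overlapping ring intervals for years %d and %d",
                     sp, d$year[ov[1L]], d$year[ov[1L] + 1L]))
      if (any(diff(d$year) <= 0))
        stop(sprintf("specimen '%s': years must increase with radial position", sp))
    }
  }
  rownames(df) <- NULL
  df
}

profile_slice <- function(profile, start_px, end_px) {
  origin <- attr(profile, "origin")
  if (is.null(origin)) origin <- 0L
  i1 <- start_px - origin + 1L
  i2 <- end_px - origin
  if (end_px <= start_px) stop("empty ring interval [", start_px, ", ", end_px, ")")
  if (i1 < 1L || i2 > length(profile))
    stop(sprintf("ring interval [%d, %d) outside profile covering [%d, %d)",
                 start_px, end_px, origin, origin + length(profile)))
  as.numeric(profile[i1:i2])
}

#' Per-ring porosity statistics
#'
#' Restricts the averaged porosity profile to one ring's radial interval and
#' computes ring width together with the maximum, mean and minimum porosity,
#' the ring descriptors used for annual time series.
#'
#' @param profile Averaged porosity profile (numeric vector, optionally with
#'   an `origin` attribute as produced by [profile_set()]).
#' @param annotation List or one-row data frame with `start_px`, `end_px` and
#'   optionally `specimen_id`, `year`.
#' @param scale_um_per_px Optional pixel size; adds `ring_width_um`.
#' @return One-row `data.frame`: `specimen_id, year, ring_width_px,
#'   (ring_width_um,) por_max, por_mean, por_min`.
#' @export
ring_stats <- function(profile, annotation, scale_um_per_px = NULL) {
  vals <- profile_slice(profile, annotation$start_px, annotation$end_px)
  out <- data.frame(
    specimen_id = if (!is.null(annotation$specimen_id)) annotation$specimen_id else NA_character_,
    year = if (!is.null(annotation$year)) annotation$year else NA_integer_,
    ring_width_px = as.integer(annotation$end_px - annotation$start_px),
    por_max = max(vals), por_mean = mean(vals), por_min = min(vals))
  if (!is.null(scale_um_per_px))
    out$ring_width_um <- out$ring_width_px * scale_um_per_px
  out
}

#' Assemble per-specimen ring series from annotations and profiles
#'
#' Matches every annotated ring to the averaged porosity profile of its image,
#' computes [ring_stats()] per ring, and returns records sorted by specimen
#' and year, plus the per-ring profile slices needed for mean annual profiles.
#'
#' @param annotations Annotation `data.frame` (validated here).
#' @param profiles Named list of averaged porosity profiles, keyed by the
#'   `image` values of the annotation table.
#' @param scale_um_per_px Optional pixel size passed to [ring_stats()].
#' @return List with `records` (one row per ring) and `ring_profiles`
#'   (list keyed `"<specimen_id>.<year>"`).
#' @export
build_series <- function(annotations, profiles, scale_um_per_px = NULL) {
  ann <- validate_ring_annotations(annotations)
  missing_img <- setdiff(unique(ann$image), names(profiles))
  if (length(missing_img))
    stop("no profile supplied for image(s): ", paste(missing_img, collapse = ", "))
  records <- do.call(rbind, lapply(seq_len(nrow(ann)), function(i)
    ring_stats(profiles[[ann$image[i]]], ann[i, ], scale_um_per_px)))
  slices <- lapply(seq_len(nrow(ann)), function(i)
    profile_slice(profiles[[ann$image[i]]], ann$start_px[i], ann$end_px[i]))
  names(slices) <- paste(ann$specimen_id, ann$year, sep = ".")
  ord <- order(records$specimen_id, records$year)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  list(records = records, ring_profiles = slices[ord])
}

#' Resample a porosity profile to a target length
#'
#' Linear interpolation onto `target_length` equally spaced points over the
#' relative ring position `[0, 1]`; endpoints are preserved exactly. Used to
#' bring rings of different widths onto a common support before averaging
#' profiles across specimens within a year.
#'
#' @param values Numeric porosity profile (length >= 2).
#' @param target_length Desired length (>= 2).
#' @return Numeric vector of length `target_length`.
#' @export
compress_profile <- function(values, target_length) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("profile must have length >= 2")
  if (!is.numeric(target_length) || length(target_length) != 1L || target_length < 2)
    stop("'target_length' must be a single integer >= 2")
  target_length <- as.integer(target_length)
  if (target_length == length(values)) return(values)
  x <- seq(0, 1, length.out = length(values))
  xout <- seq(0, 1, length.out = target_length)
  approx(x, values, xout = xout, method = "linear")$y
}

#' Mean annual porosity profile across specimens
#'
#' Compresses all profiles for one calendar year to the shortest among them
#' (see [compress_profile()]) and returns their pixelwise arithmetic mean.
#'
#' @param profiles List of numeric porosity profiles (one per specimen).
#' @return Numeric mean profile with attribute `n` (number of specimens).
#' @export
mean_annual_profile <- function(profiles) {
  if (length(profiles) == 0L) stop("no profiles supplied")
  len <- min(vapply(profiles, length, integer(1)))
  if (len < 2L) stop("profiles must have length >= 2")
  compressed <- vapply(profiles, compress_profile, numeric(len), target_length = len)
  structure(rowMeans(matrix(compressed, nrow = len)), n = length(profiles))
}

#' Extract one parameter's annual series per specimen
#'
#' @param records Ring-record `data.frame` from [build_series()].
#' @param parameter One of `"RW"`, `"MEAN_Por"`, `"MAX_Por"`, `"MIN_Por"`.
#' @return Named list (one entry per specimen) of year-named numeric vectors.
#' @export
series_from_records <- function(records,
                                parameter = c("RW", "MEAN_Por", "MAX_Por", "MIN_Por")) {
  parameter <- match.arg(parameter)
  col <- switch(parameter, RW = "ring_width_px", MEAN_Por = "por_mean",
                MAX_Por = "por_max", MIN_Por = "por_min")
  out <- lapply(split(records, records$specimen_id), function(d) {
    v <- as.numeric(d[[col]]); names(v) <- d$year; v[order(d$year)]
  })
  out[order(names(out))]
}

#' Write ring records to CSV
#'
#' @param records Ring-record `data.frame` from [build_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}
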