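# Synthetic wood micrographs with known ground truth.
#
# Each ring has a target porosity function P(x) over radial position, set by
# the wood archetype and shifted year-to-year by a simulated annual signal.
# Voids are carved into the wall matrix by thresholding a smoothed Gaussian
# random field per column within 200-px tangential strata, keeping exactly
# round(stratum * P(x)) void pixels per column stratum. This stratified
# construction guarantees the generator contract: the realized void fraction
# matches P(x) to within rounding for full columns and for any scan window
# aligned to the stratum grid, while the smooth field gives the voids
# vessel-like blob geometry and tangential coherence.

#' Wood archetype for the synthetic generator
#'
#' Parameter bundle describing one of three vessel arrangements:
#' * `ring_porous` — porous earlywood (large vessels, high porosity) with a
#'   sharp transition to dense latewood several times less porous;
#' * `semi_ring_porous` — the same decline but gradual;
#' * `diffuse_porous` — even small vessels, gently declining porosity and a
#'   dense terminal band at the ring border.
#'
#' Porosity levels, transition geometry, vessel sizes (random-field smoothing
#' scales) and staining intensities are all overridable via `...`. The
#' optional high-frequency oscillation (regular tangential vessel banding,
#' as seen in fast-grown diffuse-porous shrubs) is off by default.
#'
#' @param kind Archetype name.
#' @param low_contrast If `TRUE`, use a weakly separated, noisy intensity
#'   preset (walls 110, lumens 150, noise sd 25) that stresses the threshold
#'   step; the default preset is clearly bimodal.
#' @param ... Named overrides of any archetype field.
#' @return Object of class `wood_archetype` (a named list).
#' @export
wood_archetype <- function(kind = c("ring_porous", "semi_ring_porous", "diffuse_porous"),
                           low_contrast = FALSE, ...) {
  kind <- match.arg(kind)
  a <- switch(kind,
    ring_porous = list(
      kind = kind, earlywood_fraction = 0.33, por_early = 0.55, por_late = 0.18,
      transition_steepness = 20, terminal_band = 0, slope = 0,
      vessel_sigma_early = 10, vessel_sigma_late = 5),
    semi_ring_porous = list(
      kind = kind, earlywood_fraction = 0.45, por_early = 0.50, por_late = 0.20,
      transition_steepness = 6, terminal_band = 0, slope = 0,
      vessel_sigma_early = 8, vessel_sigma_late = 4),
    diffuse_porous = list(
      kind = kind, earlywood_fraction = 0.5, por_early = 0.48, por_late = 0.15,
      transition_steepness = 100, terminal_band = 0.85, slope = 0.08,
      vessel_sigma_early = 6, vessel_sigma_late = 6))
  a <- c(a, list(
    hf_amplitude = 0, hf_period = 40,
    wall_rgb = c(90, 45, 60), lumen_rgb = c(225, 218, 228),
    noise_sd = 12))
  if (low_contrast) {
    a$wall_rgb <- c(112, 108, 112); a$lumen_rgb <- c(152, 148, 152); a$noise_sd <- 25
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(a))
  if (length(bad)) stop("unknown archetype field(s): ", paste(bad, collapse = ", "))
  a[names(dots)] <- dots
  structure(a, class = "wood_archetype")
}

#' Target porosity function of one ring
#'
#' Evaluates the archetype's porosity-vs-relative-position shape at
#' `width_px` radial pixels, shifted by `por_shift` (the ring's annual
#' anomaly) and clipped to `[0.01, 0.99]`. Ring-porous and semi-ring-porous
#' shapes are a logistic drop from earlywood to latewood porosity; the
#' diffuse-porous shape is a gentle linear decline ending in a dense terminal
#' band. If the archetype's `hf_amplitude` is positive, a sinusoidal
#' modulation with period `hf_period` pixels is superposed.
#'
#' @param archetype A [wood_archetype()].
#' @param width_px Ring width in radial pixels (>= 30).
#' @param por_shift Additive porosity anomaly for the year.
#' @return Numeric vector of length `width_px` with values in `[0.01, 0.99]`.
#' @export
ring_porosity_shape <- function(archetype, width_px, por_shift = 0) {
  stopifnot(inherits(archetype, "wood_archetype"))
  if (width_px < 30) stop("ring width must be at least 30 px")
  u <- (seq_len(width_px) - 0.5) / width_px
  a <- archetype
  if (a$kind == "diffuse_porous") {
    base <- a$por_early - a$slope * u
    drop <- (base - a$por_late) / (1 + exp(-(u - a$terminal_band) * a$transition_steepness))
    P <- base - drop
  } else {
    P <- a$por_late + (a$por_early - a$por_late) /
      (1 + exp((u - a$earlywood_fraction) * a$transition_steepness))
  }
  if (a$hf_amplitude > 0)
    P <- P + a$hf_amplitude * sin(2 * pi * seq_len(width_px) / a$hf_period)
  P <- P + por_shift
  if (any(P < -0.02) || any(P > 1.02))
    stop("infeasible porosity target: shifted profile leaves [0, 1]")
  pmin(pmax(P, 0.01), 0.99)
}

# Smoothed standard-normal random field blended between earlywood (coarse
# vessels) and latewood (fine vessels) smoothing scales, per column.
vessel_field <- function(H, W, sigma_early, sigma_late, ew_weight) {
  noise <- matrix(rnorm(H * W), H, W)
  if (abs(sigma_early - sigma_late) < 1e-9) return(smooth_matrix(noise, sigma_early))
  coarse <- smooth_matrix(noise, sigma_early)
  fine <- smooth_matrix(noise, sigma_late)
  sweep(coarse, 2, ew_weight, `*`) + sweep(fine, 2, 1 - ew_weight, `*`)
}

# Carve the void mask: per column and per tangential stratum, mark the
# round(stratum_height * P) highest field values as void.
carve_voids <- function(field, P, stratum_px) {
  H <- nrow(field); W <- ncol(field)
  mask <- matrix(FALSE, H, W)
  strata <- split(seq_len(H), ceiling(seq_len(H) / stratum_px))
  for (rows in strata) {
    sub <- field[rows, , drop = FALSE]
    n_void <- round(length(rows) * P)
    for (j in seq_len(W)) {
      n <- n_void[j]
      if (n > 0L) mask[rows[order(sub[, j], decreasing = TRUE)[seq_len(n)]], j] <- TRUE
    }
  }
  mask
}

render_panorama <- function(archetype, ring_widths, por_shifts, years,
                            height = 1800L, seed = 1L, noise_sd = archetype$noise_sd,
                            stratum_px = 200L, rgb = TRUE) {
  stopifnot(inherits(archetype, "wood_archetype"),
            length(ring_widths) == length(por_shifts),
            length(years) == length(ring_widths))
  with_seed(seed, {
    P <- unlist(lapply(seq_along(ring_widths), function(i)
      ring_porosity_shape(archetype, ring_widths[i], por_shifts[i])))
    W <- length(P); H <- as.integer(height)
    # earlywood weight per column for vessel-size blending
    base <- unlist(lapply(ring_widths, function(w) ring_porosity_shape(archetype, w, 0)))
    rng <- range(base)
    ew <- if (diff(rng) < 1e-9) rep(0.5, W) else (base - rng[1]) / diff(rng)
    field <- vessel_field(H, W, archetype$vessel_sigma_early,
                          archetype$vessel_sigma_late, ew)
    mask <- carve_voids(field, P, stratum_px)
    clamp <- function(m) pmin(pmax(round(m), 0), 255)
    gray_wall <- round(0.299 * archetype$wall_rgb[1] + 0.587 * archetype$wall_rgb[2] +
                       0.114 * archetype$wall_rgb[3])
    gray_lumen <- round(0.299 * archetype$lumen_rgb[1] + 0.587 * archetype$lumen_rgb[2] +
                        0.114 * archetype$lumen_rgb[3])
    if (rgb) {
      img <- array(0, dim = c(H, W, 3))
      for (ch in 1:3) {
        tone <- ifelse(mask, archetype$lumen_rgb[ch], archetype$wall_rgb[ch])
        img[, , ch] <- clamp(tone + if (noise_sd > 0) rnorm(H * W, sd = noise_sd) else 0)
      }
    } else {
      tone <- ifelse(mask, gray_lumen, gray_wall)
      img <- clamp(tone + if (noise_sd > 0) matrix(rnorm(H * W, sd = noise_sd), H, W) else 0)
    }
    ends <- cumsum(ring_widths)
    starts <- c(0L, ends[-length(ends)])
    truth <- data.frame(year = years, start_px = as.integer(starts),
                        end_px = as.integer(ends),
                        ring_width_px = as.integer(ring_widths),
                        por_max = NA_real_, por_mean = NA_real_, por_min = NA_real_)
    ring_P <- vector("list", length(years))
    for (i in seq_along(years)) {
      seg <- P[(starts[i] + 1L):ends[i]]
      ring_P[[i]] <- seg
      truth$por_max[i] <- max(seg); truth$por_mean[i] <- mean(seg)
      truth$por_min[i] <- min(seg)
    }
    list(image = img, mask_true = mask, P = P, truth = truth, ring_P = ring_P,
         midpoint_threshold = as.integer(floor((gray_wall + gray_lumen) / 2)))
  })
}

#' Render one synthetic growth ring
#'
#' Generates a stained-section-like image of a single ring: light vessel
#' lumens on a dark wall matrix with Gaussian pixel noise, following the
#' archetype's target porosity function. The returned ground truth contains
#' the target profile `P`, the noiseless vessel mask, and the target
#' max/mean/min porosity. Rendering is deterministic for a given seed.
#'
#' @param archetype A [wood_archetype()].
#' @param width_px Ring width in radial pixels (>= 30).
#' @param height Image height in tangential pixels.
#' @param seed Integer seed for the portable RNG.
#' @param por_shift Additive porosity anomaly (see [ring_porosity_shape()]).
#' @param noise_sd Gaussian pixel-noise standard deviation (gray levels).
#' @param rgb Render three stain-tinted channels (`TRUE`) or grayscale.
#' @param stratum_px Tangential stratum height for porosity control.
#' @return List with `image`, `mask_true` (logical, `TRUE` = void), `P`
#'   (target porosity per radial pixel), `truth` (one-row stats data frame)
#'   and `midpoint_threshold` (binarizing a noiseless rendering at this
#'   gray level reproduces `mask_true` exactly).
#' @export
render_ring <- function(archetype, width_px, height = 1800L, seed = 1L,
                        por_shift = 0, noise_sd = archetype$noise_sd,
                        rgb = TRUE, stratum_px = 200L) {
  render_panorama(archetype, ring_widths = width_px, por_shifts = por_shift,
                  years = 1L, height = height, seed = seed,
                  noise_sd = noise_sd, stratum_px = stratum_px, rgb = rgb)
}

#' Simulate annual ring statistics for a specimen cohort
#'
#' Generates the ground-truth annual signal of a simulated site: each
#' specimen's yearly porosity anomaly is
#' `por_sd * (sqrt(s) * common_year_effect + sqrt(1 - s) * specimen_effect)`
#' with standard-normal effects, so the expected inter-series correlation of
#' the porosity parameters equals the signal share `s`. Ring widths follow
#' the same construction with their own signal share, independent of the
#' porosity signal. Anomalies are truncated at 2.4 standard deviations so
#' shifted porosity targets stay renderable.
#'
#' @param n_specimens Number of specimens.
#' @param n_years Series length in years.
#' @param signal_share Common-signal share `s` in `[0, 1]` for porosity.
#' @param start_year First calendar year.
#' @param por_sd Interannual standard deviation of the porosity anomaly.
#' @param rw_mean,rw_sd Ring-width mean and interannual sd, pixels.
#' @param rw_signal_share Common-signal share for ring width.
#' @param seed Integer seed.
#' @return List with `years`, `signal_share`, per-year `common` effects, and
#'   `specimens`: a named list with `por_shift` and `ring_width_px` vectors.
#' @export
simulate_annual_stats <- function(n_specimens = 12L, n_years = 30L,
                                  signal_share = 0.5, start_year = 1991L,
                                  por_sd = 0.05, rw_mean = 150, rw_sd = 25,
                                  rw_signal_share = 0.3, seed = 1L) {
  stopifnot(n_specimens >= 1, n_years >= 2,
            signal_share >= 0, signal_share <= 1)
  with_seed(seed, {
    years <- start_year + seq_len(n_years) - 1L
    zc <- rnorm(n_years); zc_rw <- rnorm(n_years)
    trunc24 <- function(z) pmin(pmax(z, -2.4), 2.4)
    specimens <- lapply(seq_len(n_specimens), function(i) {
      zi <- rnorm(n_years); zi_rw <- rnorm(n_years)
      shift <- por_sd * trunc24(sqrt(signal_share) * zc + sqrt(1 - signal_share) * zi)
      rw <- round(pmax(rw_mean + rw_sd * trunc24(
        sqrt(rw_signal_share) * zc_rw + sqrt(1 - rw_signal_share) * zi_rw), 40))
      list(por_shift = stats::setNames(shift, years),
           ring_width_px = stats::setNames(as.integer(rw), years))
    })
    names(specimens) <- sprintf("S%02d", seq_len(n_specimens))
    list(years = years, signal_share = signal_share,
         common = stats::setNames(zc, years), specimens = specimens)
  })
}

#' Render a multi-year specimen panorama
#'
#' Concatenates one rendered ring per year radially (pith to bark) with known
#' boundaries, producing the panorama image, its ring annotations, and the
#' ground-truth per-ring statistics.
#'
#' @param archetype A [wood_archetype()].
#' @param annual One specimen's entry from [simulate_annual_stats()] (a list
#'   with year-named `por_shift` and `ring_width_px`); if `NULL`, a
#'   single-specimen simulation with default parameters is drawn from `seed`.
#' @param specimen_id Label used in annotations.
#' @param image_name Image file name recorded in the annotations.
#' @param height,seed,noise_sd,rgb,stratum_px As in [render_ring()].
#' @return List with `image`, `mask_true`, `annotations` (data frame with
#'   `specimen_id, year, image, start_px, end_px`), `truth` (per-ring target
#'   stats), `ring_P` (target profiles) and `midpoint_threshold`.
#' @export
render_specimen <- function(archetype, annual = NULL, specimen_id = "S01",
                            image_name = paste0(specimen_id, ".png"),
                            height = 1800L, seed = 1L,
                            noise_sd = archetype$noise_sd, rgb = TRUE,
                            stratum_px = 200L) {
  if (is.null(annual))
    annual <- simulate_annual_stats(n_specimens = 1L, seed = seed)$specimens[[1L]]
  years <- as.integer(names(annual$por_shift))
  if (length(years) < 2L) stop("a specimen needs at least two years")
  pan <- render_panorama(archetype, ring_widths = as.integer(annual$ring_width_px),
                         por_shifts = as.numeric(annual$por_shift), years = years,
                         height = height, seed = seed, noise_sd = noise_sd,
                         stratum_px = stratum_px, rgb = rgb)
  ann <- data.frame(specimen_id = specimen_id, year = years, image = image_name,
                    start_px = pan$truth$start_px, end_px = pan$truth$end_px)
  truth <- cbind(specimen_id = specimen_id, pan$truth)
  list(image = pan$image, mask_true = pan$mask_true, annotations = ann,
       truth = truth, ring_P = pan$ring_P, midpoint_threshold = pan$midpoint_threshold)
}

#' Render a cohort of specimens sharing an annual signal
#'
#' Simulates a site's annual signal with [simulate_annual_stats()] and renders
#' each specimen's panorama with [render_specimen()]. Optionally writes the
#' fixture set to disk: one PNG per specimen, a combined `RINGS.csv`
#' annotation table, and a `truth.json` manifest sufficient to recompute
#' every expected pipeline output without the images.
#'
#' @inheritParams simulate_annual_stats
#' @param archetype A [wood_archetype()].
#' @param height,noise_sd,rgb,stratum_px As in [render_ring()].
#' @param dir If non-`NULL`, write images, annotations and manifest here.
#' @param ... Further arguments to [simulate_annual_stats()].
#' @return List with `specimens` (per-specimen render results),
#'   `annotations` (combined), `truth` (combined per-ring stats), `stats`
#'   (the simulated signal) and `dir`.
#' @export
render_site <- function(archetype, n_specimens = 12L, n_years = 30L,
                        signal_share = 0.5, seed = 1L, height = 1800L,
                        noise_sd = archetype$noise_sd, rgb = FALSE,
                        stratum_px = 200L, dir = NULL, ...) {
  stats_sim <- simulate_annual_stats(n_specimens = n_specimens, n_years = n_years,
                                     signal_share = signal_share, seed = seed, ...)
  spec_seeds <- with_seed(seed, sample.int(2^30, n_specimens))
  specimens <- vector("list", n_specimens)
  names(specimens) <- names(stats_sim$specimens)
  for (i in seq_len(n_specimens)) {
    id <- names(stats_sim$specimens)[i]
    specimens[[i]] <- render_specimen(archetype, annual = stats_sim$specimens[[i]],
                                      specimen_id = id, height = height,
                                      seed = spec_seeds[i], noise_sd = noise_sd,
                                      rgb = rgb, stratum_px = stratum_px)
  }
  annotations <- do.call(rbind, lapply(specimens, `[[`, "annotations"))
  truth <- do.call(rbind, lapply(specimens, `[[`, "truth"))
  rownames(annotations) <- rownames(truth) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n_specimens))
      write_image_png(specimens[[i]]$image,
                      file.path(dir, specimens[[i]]$annotations$image[1L]))
    write.csv(annotations, file.path(dir, "RINGS.csv"), row.names = FALSE)
    manifest <- list(archetype = archetype$kind, signal_share = signal_share,
                     seed = seed, height = height, noise_sd = noise_sd,
                     years = stats_sim$years, truth = truth)
    jsonlite::write_json(manifest, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(specimens = specimens, annotations = annotations, truth = truth,
       stats = stats_sim, dir = dir)
}
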