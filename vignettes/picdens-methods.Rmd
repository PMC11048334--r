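---
title: "Pixel-contrast densitometry: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pixel-contrast densitometry: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picdens)
```

## The measurement model

Pixel-contrast densitometry treats a micrograph of a stained wood
cross-section as a grid of points that belong either to cell-wall material or
to void space (vessel and fibre lumens, intercellular spaces). The quantity
measured is the **porosity**

$$\mathrm{Por}(x) \;=\; \frac{\text{void pixels on the scanning line at radial position } x}{\text{total pixels on the scanning line}},$$

a unitless fraction in $[0, 1]$. Porosity is the complement of the relative
wall area; multiplying the wall fraction by a wood-matter density would yield
a conventional density estimate, but that conversion is deliberately not
performed here: sections fixed in glycerol have swollen, variably hydrated
walls, so the unitless porosity is the robust observable.

The pipeline makes three modelling assumptions worth stating explicitly:

* **Two-phase image**: after staining, wall and void pixels form two
  distinguishable intensity populations, so the gray-level histogram is
  bimodal and a single global threshold separates them. Local/adaptive
  thresholding is intentionally out of scope — structural disturbances are
  handled by replicate scan areas, not by segmentation.
* **Axis-aligned geometry**: the radial (pith-to-bark) direction runs along
  image columns and ring boundaries are approximately parallel to image
  rows. Rings with strongly curved boundaries (typically the first years
  near the pith) violate this and should be excluded at annotation time; the
  package does not deskew.
* **Annotated boundaries**: ring limits are user-supplied half-open pixel
  intervals `[start_px, end_px)`. No automatic boundary detection is
  attempted; an earlywood/latewood split criterion is likewise left out.

## The processing chain and its tunable parameters

**Gaussian smoothing** (`gaussian_smooth()`, default `sigma = 2` px). Global
thresholding is sensitive to pixel noise; smoothing before binarization
removes salt-and-pepper misclassifications and yields cleaner wall contours.
The kernel is the normalized discrete Gaussian with radius
$\lceil 3\sigma \rceil$; borders are mirror-reflected so constant regions are
preserved exactly, and each RGB channel is smoothed independently *before*
grayscale conversion. The value 2 px is a conventional denoising choice for
images whose smallest structures (fibre lumens) are an order of magnitude
larger than a pixel; it is exposed everywhere as a parameter. With `sigma`
well below the smallest lumen radius the porosity bias introduced by edge
blurring stays within about 0.01 (measured on the synthetic benchmark); a
`sigma` approaching the lumen scale erodes small latewood vessels and biases
latewood porosity low.

**Grayscale conversion** (`to_grayscale()`). Fixed ITU-R BT.601 luma weights
(0.299, 0.587, 0.114), rounded to integers. The exact weighting matters less
than its fixity: any reasonable luminance projection keeps the two stain
populations separated, but a reproducible pipeline must pin one down.

**Otsu threshold** (`otsu_threshold()`). The split $t \in [0, 254]$
minimizing the intra-class variance
$\sigma_\omega^2(t) = \omega_1 \sigma_1^2 + \omega_2 \sigma_2^2$ over the
dark class (levels $\le t$) and light class (levels $> t$), computed per
image so staining intensity differences between slides do not propagate.
Implementation notes: only splits with two non-empty classes are candidates;
ties — which occur whenever the histogram has an empty valley — are broken
toward the smallest threshold, making the output deterministic; a
single-level histogram is rejected with an error rather than silently
classified. The equivalence with between-class-variance maximization and the
decomposition *within + between = total* are both exercised in the tests.

**Binarization** (`binarize()`). Light pixels (above threshold) become void,
dark pixels wall, matching sections where lignified walls stain dark. For
inverted material a polarity flag flips the classes.

**The virtual sensor** (`scan_profile()`, `profile_set()`). A scanning line
one pixel thick and `window` pixels long (default 1000) advances along the
radial axis in one-pixel steps; each position yields one exact integer count
ratio. The line is replicated at five tangential offsets 200 px apart
(`make_scan_areas()`), and the **averaged profile** is defined as the
pixelwise mean of the five window profiles — not a single count over the
union of rows, which would weight overlapping rows unevenly. The 1000-px
window is wide enough to span several rows of large earlywood vessels in
ring-porous wood, so single structural features (rays, giant vessels, local
damage) cannot dominate any one profile; the correlation of each window
profile with the average (`profile_correlation_table()`) is the standard
check that the windows share one radial signal. Images shorter than the
window fall back to a single full-height window with a warning.

**Ring statistics and series** (`ring_stats()`, `build_series()`). Per ring:
width (interval length along the scan axis, optionally scaled to µm) and the
maximum, mean and minimum of the averaged profile over the ring interval.
Statistics are computed on the averaged profile rather than per window,
matching the view that the five windows are replicate measurements of one
ring. For cross-specimen profile averaging within a year
(`mean_annual_profile()`), profiles are first compressed to the shortest
ring of that year by linear interpolation on relative ring position
(`compress_profile()`) — the simplest monotone, endpoint-preserving
resampling consistent with "compression"; it is exactly idempotent and
commutes with constant shifts.

**Chronology statistics** (`pearson_test()`, `interseries_correlation()`,
`site_chronology()`, `parameter_correlation_matrix()`). All comparisons are
Pearson correlations on pairwise-complete year overlaps (minimum 3 years;
shorter overlaps are dropped with a warning, never imputed), with two-tailed
significance from $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df. The mean
inter-series correlation of a parameter is the average over all specimen
pairs; the leave-one-out alternative (each series against the mean of the
others, the dendrochronological rbar convention) is available via
`method = "mean_chronology"`. Parameter-level correlation matrices are
computed between site chronologies and report raw p-values at
$\alpha = 0.05$ — no multiple-testing correction, since only six pairs are
involved and the matrix is descriptive.

## The synthetic benchmark

Real calibration material for this instrument — micrographs with
independently known porosity — essentially does not exist, so the package
ships a generator whose ground truth is exact by construction.

Each archetype defines a target porosity function $P(x)$ over relative ring
position:

* `ring_porous`: logistic drop from 0.55 (earlywood vessel zone, first third
  of the ring) to 0.18 (dense latewood), a porosity ratio of ~3, matching
  the "sharp transition, several-fold lower latewood porosity" morphology;
* `semi_ring_porous`: the same endpoints with a gradual transition;
* `diffuse_porous`: a gentle linear decline from 0.48 with a dense terminal
  band (0.15) occupying the last ~15% of the ring.

An optional sinusoidal modulation (amplitude/period) models the regular
tangential vessel banding of fast-growing diffuse-porous shrubs; it is off
by default.

**Rendering.** Voids are carved from a smoothed standard-normal random field
(vessel-shaped blobs; the smoothing scale sets vessel size and is blended
from an earlywood scale to a latewood scale across the ring). Within each
image column and each 200-px tangential stratum, exactly
$\mathrm{round}(200\,P(x))$ pixels with the highest field values become
void. This **stratified porosity control** is the generator's key design
choice: realized void fractions match $P(x)$ to within rounding (±0.0025)
not only per full column but for every scan window aligned to the stratum
grid, so profile-level validation isolates the error contributed by the
*pipeline* (blur, thresholding) rather than by generator shot noise. Void
and wall pixels then receive stain-like RGB tones (walls ≈ (90, 45, 60),
lumens ≈ (225, 218, 228); BT.601 grays 60 and 221) plus Gaussian noise
(default sd 12 gray levels), giving a clearly bimodal histogram; a
low-contrast preset (tones 40 levels apart, noise sd 25) is available to
stress the threshold step. Binarizing a noiseless rendering at the tone
midpoint reproduces the vessel mask bit-exactly, which the tests verify.

The default vessel scales (field sigma 10/5 px for ring-porous
earlywood/latewood, 8/4 semi-ring-porous, 6 diffuse) keep the smallest
lumens comfortably larger than the default smoothing kernel — consistent
with 400× micrographs, where even fibre lumens span tens of pixels — so the
binarization bias of the full chain stays below ~0.02 porosity units.

**Cohorts.** `simulate_annual_stats()` draws each specimen's annual porosity
anomaly as $\sigma_a(\sqrt{s}\,c_y + \sqrt{1-s}\,e_{iy})$ with
standard-normal common ($c_y$) and specimen ($e_{iy}$) effects, anomaly sd
$\sigma_a = 0.05$ and default signal share $s = 0.5$, so the expected
inter-series correlation equals $s$; effects are truncated at 2.4 sd to keep
shifted porosity targets renderable. Ring widths get an independent signal
(share 0.3, mean 150 px, sd 25 px — within the 135–1074 px range typical of
shrub rings at 400×), deliberately uncorrelated with the porosity signal so
that porosity/width independence can be tested. `render_site()` ties the
pieces together and can emit a PNG + `RINGS.csv` + `truth.json` fixture set;
the JSON manifest alone suffices to recompute every expected pipeline
output.

**What the generator does not emulate**: rays and parenchyma bands, callus
and rupture artifacts, staining gradients within a slide, curved ring
boundaries, and optical vignetting. Passing the synthetic validation
therefore demonstrates correctness of the measurement chain under the
two-phase, axis-aligned model — it does not certify robustness to histology
defects, which real applications must manage through the multi-window
design and annotation choices.

## Numerical choices and degenerate inputs

* Integer pixel counts are exact; porosity values are ratios of integers and
  are tested for exact equality, not tolerance.
* Otsu ties → smallest threshold; single-level histograms → error.
* Images smaller than the smoothing kernel radius → error (no silent kernel
  truncation).
* Zero-variance profiles yield `NA` correlations with a warning.
* All stochastic components run through one seeded, named RNG
  (Mersenne-Twister / inversion sampling), and the caller's RNG state is
  restored afterwards; repeated seeded runs produce bit-identical images and
  CSVs.

## Validation problem sizes

The shipped validation uses sizes chosen to exercise every code path at
desk scale: 1000 random histograms for the Otsu/exhaustive-search
equivalence; 100 random masks for count exactness; single 400-px rings at
the full default scan geometry (1800 × 400 px, five 1000-px windows) for
scan-area coherence and profile recovery; one rendered cohort of 12
specimens × 30 years (≈ 4500 × 1800 px grayscale panoramas) for
ring-statistic and signal recovery; 20 replicates × 4 signal shares at the
ground-truth level for the inter-series sweep; and 10,000 replicates for the
t-test size check. The cohort image-level experiment runs once rather than
being replicated because its per-ring errors are bias-dominated (the
replicated manifest-level sweep covers sampling variability).

## Known limitations

* A global threshold assumes one staining regime per image; strong
  within-slide gradients would need per-region thresholds.
* Porosity is not converted to g/cm³; doing so requires wall-density
  assumptions that glycerol-fixed sections do not support.
* Ring boundaries and their non-parallelism are the annotator's
  responsibility; errors there propagate directly into width and porosity
  statistics.
* The inter-series correlation of short series (< 15 years) is a noisy
  estimator; the package reports overlap sizes so users can judge.
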