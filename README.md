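# picdens

Pixel-contrast (PiC) densitometry for angiosperm wood micrographs.

Wood density variation across growth rings is a classic ecological archive,
but X-ray densitometry is expensive and blue-intensity methods are limited to
conifers with regular tracheid anatomy. Pixel-contrast densitometry replaces
the physical densitometer with image analysis: a stained cross-section
photograph is separated into cell-wall pixels and void pixels (lumens and
intercellular spaces), and the fraction of void pixels — the **porosity**
`Por = A_lumen / A_scan` — is recorded along the radial axis by a virtual
sensor. The resulting intra-ring porosity profiles and their per-ring
summaries (maximum, mean and minimum porosity, plus ring width) behave like
densitometric series and can be assembled into multi-specimen chronologies
for dendroecological analysis. The approach works for ring-porous,
semi-ring-porous and diffuse-porous wood alike, where vessel arrangement —
not tracheid walls — carries the density signal.

The package is aimed at quantitative wood anatomists and dendroecologists
working from light micrographs of stained cross-sections (e.g. safranin /
Astra blue at 400×), one image per ring or a radial panorama per specimen,
plus a ring-boundary annotation table.

## Method

1. **Binarization** (`preprocess()`): Gaussian smoothing (default
   `sigma = 2` px, kernel radius `⌈3σ⌉`, reflected borders, applied per RGB
   channel), grayscale conversion with fixed BT.601 luma weights, then Otsu's
   threshold on the 256-bin gray histogram — the split `t` minimizing the
   intra-class variance `σ²_ω(t) = ω₁σ₁² + ω₂σ₂²` (ties → smallest `t`).
   Pixels above the threshold are voids, pixels at or below are walls.
2. **Virtual sensor** (`profile_set()`): a one-pixel-thick scanning line of
   length 1000 px advances column by column; five overlapping tangential
   windows (200-px step) give five replicate porosity profiles whose
   pixelwise mean is the averaged profile.
3. **Ring series** (`build_series()`, `ring_stats()`): each annotated ring
   contributes its width and the max/mean/min of the averaged profile;
   profiles of one year are compared across specimens after linear
   compression to the shortest ring (`compress_profile()`,
   `mean_annual_profile()`).
4. **Chronology statistics** (`pearson_test()`,
   `interseries_correlation()`, `site_chronology()`,
   `parameter_correlation_matrix()`): Pearson correlations with two-tailed
   t-tests (`t = r√((n−2)/(1−r²))`, df = n−2), mean pairwise inter-series
   correlations per parameter, and site-mean chronologies.
5. **Synthetic benchmark** (`wood_archetype()`, `render_ring()`,
   `render_site()`): seeded generator of wood-like images with an exactly
   known porosity function per ring and a tunable common annual signal, used
   to validate every stage end to end.

## Worked example

```r
library(picdens)

# a synthetic ring-porous growth ring, 400 px wide, with known truth
arch <- wood_archetype("ring_porous")
ring <- render_ring(arch, width_px = 400, seed = 42)

mask <- preprocess(ring$image, sigma = 2)
#> Otsu threshold: 134

pset <- profile_set(mask)          # five 1000-px windows, 200-px step
pset
#> Porosity profile set: 5 scan areas (window 1000 px), 400 radial px from pixel 0
#>   averaged porosity: mean 0.303, range [0.167, 0.567]

profile_correlation_table(pset)$r
#> [1] 0.9997677 0.9998934 0.9999247 0.9998707 0.9997840

rs <- ring_stats(pset$averaged, list(specimen_id = "demo", year = 2022,
                                     start_px = 0, end_px = 400))
rs[, c("ring_width_px", "por_max", "por_mean", "por_min")]
#>   ring_width_px por_max por_mean por_min
#> 1           400  0.5666 0.303495  0.1668
```

The five scan-area profiles correlate with their average at r > 0.999,
showing that the tangential windows measure one common radial signal; the
ring's recovered statistics match the generator's targets for this seed
(max 0.549, mean 0.302, min 0.180) to well within ±0.03.

A full cohort analysis — 12 specimens × 30 years rendered, binarized,
profiled, and reduced to chronologies — is exercised by
`scripts/acceptance.R` and in `tests/testthat/test-acceptance.R`.

## Command line

A thin CLI over the same functions lives at `inst/cli/picdens.R`:

```sh
Rscript inst/cli/picdens.R binarize INPUT.png --sigma 2 --out MASK.png
Rscript inst/cli/picdens.R profile MASK.png --window 1000 --step 200 --out PROFILES.csv
Rscript inst/cli/picdens.R stats SERIES.csv --out STATS/
Rscript inst/cli/picdens.R simulate --archetype diffuse_porous --specimens 12 --years 30 --seed 42 --out FIXTURES/
```

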