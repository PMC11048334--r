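Package: picdens
Title: Pixel-Contrast Densitometry for Angiosperm Wood Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for pixel-contrast (PiC) densitometry of stained wood
    cross-sections. Micrographs are denoised by Gaussian smoothing, converted
    to grayscale and binarized with Otsu's threshold to separate cell walls
    from voids (lumens and intercellular spaces). A one-pixel virtual sensor
    scans the binary image over overlapping tangential windows to produce
    intra-ring porosity profiles, from which per-ring statistics (width,
    maximum, mean and minimum porosity), per-specimen series and site
    chronologies are derived, together with Pearson inter-series correlation
    analyses. A synthetic wood-image generator with known ground truth
    (ring-porous, semi-ring-porous and diffuse-porous archetypes) supports
    validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    png,
    tiff,
    jsonlite
Suggests:
    jpeg,
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
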