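Package: widthscreen
Title: Single-Cell Width Morphometry and Plate-Normalised Screening for
    Rod-Shaped Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the width of membrane-stained, rod-shaped
    bacteria from fluorescence microscopy and to run genome-scale
    cell-width screens on multiwell plates. Includes a synthetic-image
    and synthetic-plate generator with known ground truth
    (spherocylindrical cells, tapered cells, minicells, chains, optics
    dialects for high-content and epifluorescence microscopes),
    medial-axis width and length measurement, spherocylinder
    surface/volume morphometrics, per-plate average-width (AWP)
    normalisation with two-tailed percentile hit calling, replicate-level
    verification statistics (nested t-tests, one-way ANOVA,
    Mann-Whitney), and generation-time estimation from OD600 growth
    curves by sliding-window log-linear regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
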