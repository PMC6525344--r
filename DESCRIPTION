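Package: onlshape
Title: Outer Nuclear Layer Deformation Morphometry from OCT Segmentation Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies three-dimensional deformation of the retinal outer
    nuclear layer (ONL) in epiretinal membrane from spectral-domain OCT
    segmentation surfaces. Builds 512x512 ONL height maps from paired ONL/OPL
    and RPE boundary grids, finds the histogram-mode reference plane, selects
    the ONL-Base iso-contour by four admissibility criteria (including
    elliptic Fourier restorability), fits the moment-method equivalent
    ellipse, and derives circularity, area ratio, axis ratio and the signed
    major-axis angle under a left-eye laterality convention. Includes cohort
    statistics (group comparisons, MCHART MH/MV ratio construction, Pearson
    correlations with an axis-window subset) and a seeded synthetic-surface
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
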