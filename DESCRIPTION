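Package: mitoscore
Title: Mito-Score Quantification of Mitochondrial Immunohistochemistry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Objective quantification of mitochondrial abundance in brightfield
    immunohistochemistry (IHC) images of formalin-fixed paraffin-embedded tissue.
    Separates DAB (brown, mitochondrial marker) signal from hematoxylin (blue)
    nuclei by windowed thresholding in HSV color space, counts nuclei by an
    Otsu-threshold / morphological-denoising / distance-map apex procedure, and
    reports the Mito-score: IHC-positive pixels per nucleus. Includes polygon
    region annotations (Labelme-style JSON), tiling of large images with per-tile
    score heatmaps, granule morphometry in physical units, a synthetic-image
    generator with exact ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
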