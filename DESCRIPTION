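Package: hamqa
Title: Quality Assessment of Ham Cold Cuts from Image Texture, Colorimetry
    and FT-IR Band Intensities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis workflow for non-destructive quality assessment of
    pork and turkey ham slices. Computes 22 grey-level texture features
    (first-order histogram statistics, 13 co-occurrence-matrix features,
    5 run-length-matrix features) from slice images, derives CIELAB
    chroma, hue angle and colour difference from colorimeter readings,
    and extracts FT-IR band intensities at 15 diagnostic mid-infrared
    regions. Ham classes (meat type and processing) are discriminated
    with a Gaussian-kernel probabilistic neural network under exhaustive
    feature-subset search and leave-one-out evaluation; refrigerated
    shelf life is monitored with quadratic storage-time trends, Spearman
    goodness of fit, and Tukey-based group comparisons with compact
    letter displays. A synthetic-data module generates class-conditioned
    images, colour readings and spectra with the documented class
    statistics so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
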