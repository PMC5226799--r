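Package: stainwave
Title: Blind Stain Deconvolution of Histology Images by Sub-Band ICA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates an image-specific stain mixing matrix for multi-stained
    histology tiles (e.g. haematoxylin and eosin) by applying independent
    component analysis to the least-Gaussian wavelet sub-bands of the
    optical-density image, then inverts the matrix to recover per-stain
    density maps. Includes a decimated orthogonal 2-D wavelet transform with
    kurtosis-based sub-band selection, resolution of ICA sign/scale/permutation
    ambiguities, a plain-ICA baseline, evaluation metrics (ground-truth stain
    matrices from annotated pixels, stain-vector distances, density-map
    correlation, Bland-Altman agreement), and a Beer-Lambert phantom generator
    with controllable inter-stain correlation for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    generics,
    ggplot2,
    ica,
    jsonlite,
    MASS,
    png,
    stats,
    tibble,
    tiff,
    utils
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
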