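Package: rainbowclass
Title: Diffraction-Rainbow Image Features and Chemometric Classification
Version: 0.1.0
Authors@R: person("rainbowclass", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for low-cost food authentication from photographs of
    diffraction-grating "rainbow" patches. Segments a rainbow patch from a
    dark-background photograph (grayscale conversion, median filtering,
    Otsu thresholding, morphological clean-up, connected-component
    selection), converts the standardized 100x100 patch into a length-100
    pseudo-spectral feature vector by weighted RGB channel combination and
    row averaging, pre-processes feature matrices (Savitzky-Golay
    smoothing, normalization, baseline correction), and classifies samples
    with k-nearest neighbours, a support vector machine with the Pearson
    VII universal kernel, PLS-DA, Gaussian-kernel PLS-DA and a locally
    weighted PLS classifier. Model selection follows a deterministic
    DUPLEX 2:1 train/test split with leave-one-out cross-validated grid
    search, reporting overall and per-class accuracy. A synthetic-data
    module generates rainbow photographs with ground truth and feature
    populations with linearly separable species structure but a nonlinear
    organic/non-organic labelling, so the whole pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
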