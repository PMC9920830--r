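Package: despeckle
Title: Speckle Noise Destruction for Breast Ultrasound Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Removal of local multiplicative speckle noise from grayscale
    ultrasound images of the breast while preserving lesion edges. Implements a
    grayscale-mean-driven piecewise contrast enhancement (logarithmic and
    exponential transforms), guided-filter detail boosting, spatial high-pass
    correction, and a compact recurrent-convolutional residual denoiser trained
    with an edge-sensitive loss. Ships a synthetic lesion-phantom generator with
    calibrated speckle and additive white Gaussian noise models, image-quality
    metrics (MSE, SNR, PSNR, edge preservation index, false-recognition rate),
    and a reproducible end-to-end pipeline with file-based configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    png,
    tiff,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
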