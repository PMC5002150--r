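Package: petiq
Title: PET Image Quality as a Function of Detected Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates reduced-dose PET acquisitions by binomial thinning of
    list-mode event streams, reconstructs multi-realization image ensembles
    (linear binning backend and a 2D OP-OSEM surrogate), delineates volumes of
    interest, computes ensemble image-quality metrics (SNR, CNR, bias, COV,
    STE), fits sensitivity-corrected SNR^2-versus-counts and normalized
    CNR-versus-counts models, and derives the minimum number of detected
    counts needed to keep each error metric below a target level. Includes a
    digital thorax phantom generator so the whole pipeline runs without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    Matrix,
    minpack.lm,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
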