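Package: dissosurrogate
Title: Spectroscopy-Based Surrogate Prediction of Tablet Dissolution Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric surrogate for in vitro dissolution testing of
    extended-release matrix tablets. Partial least squares (NIPALS) models
    quantify drug and hydroxypropyl methylcellulose content from NIR and
    Raman spectra after standard pretreatments (asymmetric least squares
    baseline, standard normal variate, multiplicative signal correction,
    Savitzky-Golay derivatives, region exclusion), optionally refined by
    genetic-algorithm wavelength-window selection with contiguous-block
    cross-validation. The predicted composition and the measured compression
    force feed a feed-forward neural network (Levenberg-Marquardt or
    Bayesian-regularization training) that outputs a 53-point dissolution
    profile, benchmarked against a direct PLS baseline with the f2
    similarity factor. A synthetic tablet, spectrum and dissolution-curve
    generator emulating the underlying factorial study makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
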