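Package: SERSQuant
Title: Quantification of Pesticide Residues from Surface-Enhanced Raman Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric workflow for quantifying pesticide residues (thiram)
    on fruit surfaces from surface-enhanced Raman spectroscopy (SERS) data.
    Provides a SummarizedExperiment-based container for spectra, a pseudo-Voigt
    spectrum simulator with fluorescence baseline and multiplicative noise,
    Savitzky-Golay smoothing and derivatives, iterative-polynomial and
    asymmetric-least-squares baseline correction, deterministic max-min
    (Kennard-Stone style) calibration/prediction splitting, kernel principal
    component analysis with a radial-basis-function kernel, and a quantitation
    layer with NIPALS partial least squares, multiple linear regression,
    cross-validated RMSECV, calibration curves, limit of detection and
    relative standard deviation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Matrix,
    signal,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
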