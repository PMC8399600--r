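Package: tpcNIR
Title: Total Polyphenolic Content Prediction from Near-Infrared Spectra of
    Sorbent-Bound Phenols
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric pipeline for quantifying total polyphenolic content
    (as gallic acid equivalents) from near-infrared diffuse-reflectance
    spectra of polyphenols adsorbed on an insoluble polyvinylpyrrolidone
    solid phase. Provides an S4 container for spectra sets built on
    SummarizedExperiment, spectral pretreatment operators (standard normal
    variate, multiplicative scatter correction, detrending, Savitzky-Golay
    smoothing and derivatives), region selection and replicate averaging,
    NIPALS PLS1 regression with leave-one-out cross-validation, multivariate
    limit-of-detection and limit-of-quantification figures of merit based on
    sensitivity and background leverages, method-validation statistics
    (recovery, relative standard deviation, confidence intervals,
    selectivity summaries), calculators for Folin-Ciocalteu and Loewenthal
    reference methods and sorbent adsorption capacity, and a synthetic
    spectra generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
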