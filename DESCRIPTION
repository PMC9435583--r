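Package: seizfc
Title: Seizure Subtype Classification from MEG Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Pipeline for classifying focal-seizure subtypes (complex versus
    simple partial seizures) from resting-state MEG parcel time series.
    Provides segment extraction with spike-window exclusion, zero-phase
    band-pass and notch filtering with downsampling, per-segment functional
    connectivity by the band-averaged imaginary part of coherency,
    F-score feature ranking with top-fraction selection, RBF-kernel SVM
    classification under subject-subset leave-one-out and random-split
    cross-validation, overlap-rate stability selection of discriminative
    cortical edges, and a synthetic lag-coupled cohort generator for
    end-to-end validation when no recordings are available.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    e1071,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
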