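Package: ecogstate
Title: Decoding Naturalistic Behavioral States from ECoG Band-Power Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Pipeline for classifying coarsely labeled naturalistic behavioral
    states (talking, watching TV, using electronics) from multichannel
    intracranial (ECoG) recordings. Implements standard ECoG preprocessing
    (median DC removal, 1-200 Hz bandpass, line-noise notches, downsampling,
    common-median reference), Hilbert-envelope band-power features averaged in
    10-s bins with artifact-based segment rejection, Gaussian electrode-to-ROI
    projection, shared-covariance linear discriminant analysis under a
    temporally buffered cross-validation scheme, finite-sample chance levels,
    Benjamini-Hochberg FDR control, class-mean consistency statistics, and
    incremental region-of-interest additivity analysis. A seedable synthetic
    recording generator with known planted spectro-spatial effects provides a
    parameter-recovery test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    yaml,
    jsonlite,
    data.table
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
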