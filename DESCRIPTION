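Package: platecal
Title: Modelling Agonist-Induced Platelet Cytosolic Calcium Time Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling calibrated cytosolic calcium concentration
    time curves of agonist-stimulated blood platelets. Provides an
    experimental-design encoder for agonist/inhibitor condition matrices, a
    phenomenological synthetic-curve generator, preprocessing (linear
    resampling to 1 s steps, Savitzky-Golay smoothing, per-curve min-max
    scaling, quadratic feature expansion), scalar curve-shape descriptors
    (magnitude, peak time, terminal level, mean absolute deviation from
    linear), a single-hidden-layer rectifier network predicting log-scaled
    curve magnitude, a closed-loop NARX recurrent network predicting the
    scaled curve trend, combined nanomolar curve reconstruction with
    one-at-a-time sensitivity sweeps, and mean-centered NIPALS partial least
    squares regression with loading-weight interpretation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    minpack.lm,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
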