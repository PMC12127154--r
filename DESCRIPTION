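Package: causalecg
Title: Backdoor-Adjusted Causal Attention Networks for Multi-Label ECG
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multi-view convolutional encoding of multi-lead ECG recordings,
    dual-kernel time-domain feature embedding, class-average confounder
    dictionaries, and a backdoor-adjusted classification head based on the
    normalized weighted geometric mean (NWGM) approximation of the causal
    intervention distribution P(Z|do(X)). Includes readers for WFDB, CSV and
    dense-array recordings, a synthetic generator of confounded ECG
    populations with controllable label-confounder correlation, a seeded
    training loop with per-epoch confounder-dictionary refresh, multi-label
    evaluation metrics, and a confounder-shift robustness protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
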