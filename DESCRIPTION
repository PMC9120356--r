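Package: mifuse
Title: Few-Channel Motor-Imagery EEG Decoding with Time-Frequency Channel
    Expansion and Evidential Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decodes binary (left/right hand) motor imagery from three-channel
    EEG (C3, Cz, C4). Each channel is expanded into multiple component channels
    by three time-frequency decompositions (wavelet packet transform, ensemble
    empirical mode decomposition, local mean decomposition), further expanded
    by delay-coordinate phase-space embedding, and classified with common
    spatial pattern features and probabilistic support vector machines whose
    per-branch outputs are fused at the decision level with Dempster-Shafer
    evidence theory. Includes a synthetic generator of event-related
    desynchronization EEG, a repeated stratified cross-validation harness with
    accuracy and Cohen's kappa, and a concatenated-feature fusion baseline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    graphics,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
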