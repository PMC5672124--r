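Package: lfpdecode
Title: Movement Decoding from Deep-Brain Local Field Potentials with
    Ensemble Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decodes voluntary finger movements and their laterality from
    bilateral deep-brain local field potential (LFP) recordings. Implements
    the full offline pipeline: a synthetic LFP session simulator with
    band-specific event-related (de)synchronization, zero-phase Chebyshev
    low-pass / 50 Hz notch / 256 Hz resampling preprocessing, level-5
    discrete-Meyer wavelet packet band decomposition with Hilbert envelope
    features, three base neural network classifiers (feedforward
    backpropagation, radial basis function, probabilistic), majority-voting
    decision fusion, a two-stage rest/left/right decoder, nearest-neighbor
    weighted bootstrap class balancing, stratified 10-fold cross-validation,
    and an evaluation-statistics suite (accuracy, sensitivity, specificity,
    F-measure, g-means, desirability, MCC, AUC, balanced accuracy, Cohen's
    kappa with standard error).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
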