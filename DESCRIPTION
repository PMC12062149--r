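Package: htrcca
Title: Hybrid Task-Related Component and Canonical Correlation Analysis for SSVEP Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frequency recognition for steady-state visual evoked potential (SSVEP)
    brain-computer interfaces. Implements the hybrid H-TRCCA recognizer, which
    trains four canonical-correlation-analysis (CCA) spatial filters and one
    task-related component analysis (TRCA) filter per stimulus and sub-band,
    selects candidate stimuli at test time by clustering per-stimulus correlation
    features (Gaussian mixture model selection of the cluster count via the
    Davies-Bouldin index, then k-means++), and fuses CCA- and TRCA-derived scores
    to pick the target frequency. Ships CCA, TRCA, eTRCA and eH-TRCCA baselines,
    a Chebyshev Type-I filter bank with weighted sub-band fusion, a
    leave-one-block-out evaluation harness with accuracy and information transfer
    rate, and a synthetic SSVEP simulator emulating benchmark-style epoched EEG.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    mclust,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
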