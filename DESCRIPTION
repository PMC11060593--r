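Package: milbench
Title: Weakly Supervised Bag Classification Benchmarks with Synthetic Cytology-Proxy Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained benchmark framework for comparing weakly supervised
    learners on bag-structured image data, modeled on liquid-based cytology
    whole-slide screening where only per-patient labels exist. Provides a
    seeded generator of synthetic bag datasets (colorized glyph images with
    per-instance ground-truth key flags, truncated normal/skew-normal channel
    color models, fixed or beta-distributed key-instance fractions), two
    learners trained end-to-end on weak labels -- a single-instance CNN
    classifier with fifth-percentile bag thresholding, and attention-based
    multiple instance learning with within-bag sampling (mini-bags drawn with
    replacement, majority-voted bag labels, aggregated attention weights) --
    plus the matching evaluation protocol: patient-level bag accuracy,
    instance-level Precision@K, 9-fold patient-level cross-validation, and
    score-ranked image mosaics. Includes a compact CPU convolutional network
    engine so that no external deep-learning runtime is required.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
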