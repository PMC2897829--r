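Package: germcnv
Title: Classifying Germline Copy Number Variants Versus Somatic Alterations in Tumor Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Distinguishes germline copy number variants (CNVs) from somatic
    copy number alterations (CNAs) among short gain/loss segments called on
    tumor copy-number arrays. Implements candidate extraction from segmented
    log-ratio profiles (MAD-based gain/loss calling, run merging, the 2.3 Mb
    candidate rule), probe-level overlap scores against a Database of Genomic
    Variants style catalogue, paired-normal truth labeling with a conditional
    segmentation permutation test, a 16-predictor feature set, hard-coded
    published decision trees alongside trainable CART and random-forest
    classifiers, evaluation utilities, and a synthetic paired tumor/normal
    cohort generator for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    rpart,
    randomForest,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
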