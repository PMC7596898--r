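Package: sparsebci
Title: Sparse-Representation and Residual-Network Classification of Motor-Imagery EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-class motor-imagery electroencephalography (EEG)
    classification. Implements epoch segmentation and zero-phase band-pass
    filtering, common spatial patterns (CSP) feature extraction, sparse
    representation classification (SRC) over a redundant dictionary of
    training features solved by L1-norm basis pursuit, and a fast-compression
    residual convolutional network (FCRes-CNN) that classifies the sparse
    codes. Includes a synthetic motor-imagery EEG generator with planted
    spatial band-power structure so every stage of the pipeline can be
    exercised and validated without external recordings, plus an evaluation
    harness comparing the SRC baseline against the SRC + FCRes-CNN pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
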