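Package: valveweak
Title: Weak Supervision Pipeline for Aortic Valve Malformation Classification
    from Phase-Contrast Cardiac MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for training bicuspid vs. tricuspid aortic valve (BAV/TAV)
    classifiers from unlabeled phase-contrast cardiac MRI sequences using weak
    supervision. Provides a seeded synthetic phantom generator emulating
    phase-contrast flow sequences, variance-based aorta localization and
    peak-flow alignment, Otsu-mask shape primitives, threshold labeling
    functions, a factor-graph generative label model fitted by persistent
    contrastive divergence with Gibbs sampling, a noise-aware convolutional
    recurrent sequence classifier with soft attention trained on probabilistic
    labels, ranking and classification metrics, and an end-to-end pipeline
    with reproducibility manifests.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
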