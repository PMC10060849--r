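Package: hofcnet
Title: Multi-Layer Functional Connectivity Networks for Multi-Site Brain
    Disorder Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds low-order (Pearson), topographical high-order and
    associated high-order functional connectivity networks from regional
    fMRI time series, selects discriminative edges with two-sample t-tests,
    fuses multi-layer edge features, and classifies subjects with a linear
    support vector machine or a domain-adversarial neural network (gradient
    reversal, class-weighted binary cross-entropy) under leave-one-site
    cross-validation. Includes a synthetic multi-site cohort generator with
    controllable group and site effects so the full pipeline is testable
    without access-restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
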