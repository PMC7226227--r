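Package: TMEMscore
Title: Automated Scoring of Tumor Microenvironment of Metastasis Doorways
    in Triple-Stained Histology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and scores Tumor MicroEnvironment of Metastasis
    (TMEM) doorways -- triads of a Mena-overexpressing tumor cell, a
    macrophage, and a blood-vessel endothelial cell in direct contact --
    in triple-immunohistochemistry RGB histology images. The pipeline
    unmixes the three chromogens plus counterstain into stain feature
    channels, classifies every pixel with a linear Bayesian (Gaussian
    linear discriminant) classifier, applies a morphometric
    reclassification cascade based on object size and perimeter-contact
    fractions to find TMEM-associated vessels and macrophages, and scores
    each case as the sum of TMEM doorway counts over the ten
    highest-ranked high-power fields, with low/intermediate/high risk
    categories. A synthetic-slide generator with planted triads,
    distractors, and pixel-level ground truth supports training and
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    tools,
    EBImage,
    jsonlite,
    yaml,
    png,
    tiff,
    mgcv,
    withr
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
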