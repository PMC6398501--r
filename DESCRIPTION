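Package: aggscreen
Title: Image-Based High-Content Screening of Protein Aggregation Modifiers
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantification of intracellular protein aggregation in image-based
    RNAi screens and in 3D confocal stacks of the larval brain. Provides a
    synthetic two-channel field and 3D stack simulator with planted ground
    truth, nuclei segmentation with per-cell region-of-interest construction,
    per-cell fluorescence intensity features, macro-equivalent cell and
    aggregate-positive counting, hit calling from per-cell intensity
    distributions via a signed two-sample Kolmogorov-Smirnov statistic with
    robust plate Z-scores and Monte-Carlo calibrated thresholds under a
    two-of-three replicate rule, and aggregate density estimation (objects per
    cubic micrometre) in the ventral nerve cord with control normalization and
    ANOVA / Fisher's LSD group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
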