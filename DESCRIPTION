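Package: rnflpca
Title: Unsupervised Structural Feature Analysis of Wide-Angle RNFL Thickness Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for eigen-image analysis of wide-angle retinal nerve fiber
    layer (RNFL) thickness maps in glaucoma. Provides a synthetic longitudinal
    cohort generator for method validation, laterality normalization and
    landmark/intensity-based image registration (including an enhanced
    correlation coefficient maximizer), per-pixel standardization, principal
    component feature extraction, age-adjusted association testing,
    participant-based leave-one-out glaucoma detection with age-controlled
    bootstrap AUC comparison, and mixed-effects normative rate-of-change
    criteria for labeling and predicting glaucomatous progression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
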