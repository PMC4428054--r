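Package: teratoMorph
Title: Quantitative Morphometric Teratogen Screening with Micropatterned
    hPSC Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements a quantitative morphometric assay for in vitro
    teratogen detection based on micropatterned human pluripotent stem cell
    (hPSC) colonies. Differentiating colonies form an annular mesoendoderm
    (BRACHYURY-positive) ring displaced about 200 micrometres inward from the
    colony edge; teratogens disrupt this pattern dose-dependently. The package
    segments whole-colony fluorescence images (multilevel Otsu thresholding),
    extracts a 19-attribute morphometric feature vector describing the
    T-positive region, compresses correlated features into morphologic
    clusters by complete-linkage correlation clustering, determines each
    compound's disruption concentration (DC) by per-cluster one-way ANOVA with
    Bonferroni-corrected post-hoc t-tests, estimates cytotoxicity IC25 by
    four-parameter logistic regression, and classifies compounds as teratogenic
    when DC < IC25 on embryonic cells. A synthetic-image generator with ground
    truth masks, plus kymograph construction from time-lapse stacks, make the
    whole pipeline testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    e1071,
    minpack.lm,
    jsonlite,
    ape,
    tiff
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
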