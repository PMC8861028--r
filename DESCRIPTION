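Package: tarsalct
Title: In Vivo Micro-CT Volumetry of the Mouse Tarsus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of bone volume (BV) and soft-tissue volume (STV)
    in the mouse tarsal region from reconstructed micro-CT volumes:
    principal-axis reorientation, landmark-anchored 100-slice (1.8 mm) volume
    of interest, fixed-threshold bone segmentation (> 3500 AU) and smoothed
    window soft-tissue segmentation (-300 to 1500 AU after a 0.1 mm Gaussian
    filter), plus the accompanying statistical layer for longitudinal
    three-group collagen-induced arthritis cohorts: mixed-effects and two-way
    ANOVA group contrasts, Kruskal-Wallis and Dunn tests on ordinal
    histopathology scores, and in vivo versus ex vivo agreement regression.
    Includes a synthetic phantom and cohort generator with exact ground truth
    so the whole pipeline is testable without scanner data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
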