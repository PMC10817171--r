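Package: myoqt1
Title: Quantitative T1 Mapping of the Myometrium with Manual and
    Semiautomatic ROI Placement
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantitative T1 (qT1) measurement of the uterine
    myometrium from variable-flip-angle spoiled gradient echo (SPGR) MRI.
    Provides digital uterus phantoms with simulated inversion-recovery and
    SPGR acquisitions, per-pixel two-point VFA T1 fitting with B1
    correction, a manual region-of-interest (ROI) protocol (whole-uterus
    contour minus endometrial contour), a semiautomatic ROI algorithm
    (seeded endometrial region growing, band sampling, +/-1.96 SD
    myometrial extraction and exhaustive translation registration by
    minimum sum of squared deviations), and an inter/intra-rater agreement
    battery: per-subject coefficient of variation and pairwise error,
    average-measures intraclass correlation with F-based confidence
    intervals, Bland-Altman analysis with proportional-bias testing,
    Wilcoxon signed-rank and paired t comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    jpeg,
    png,
    readxl,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
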