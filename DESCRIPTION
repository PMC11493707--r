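Package: ejpnet
Title: Quantification of Epithelial Junction Protein Net Integrity in
    Immunofluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the integrity of the net-like structures formed by
    epithelial junction proteins (desmoglein-1, claudin-1, ZO-1, E-cadherin)
    in immunofluorescence images of stratified squamous epithelium such as
    the ectocervix. Provides contrast-independent enhancement of curvilinear
    strand structures, segmentation of the epithelial compartment into
    superficial, intermediate and basal layers, mean fluorescence intensity
    and Euclidean distance-transform height measurements, a one-pixel break
    rule for classifying junction nets as intact or fragmented, digital
    flooding from the apical border to delineate the theoretically accessible
    region, and a partition of the intermediate layer into intact and
    fragmented regions. Includes a synthetic epithelium and cohort
    generator with known ground truth, and Spearman correlation analysis of
    image metrics against plasma hormone levels with lower-limit-of-detection
    substitution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    rlang,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    png,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
VignetteBuilder: knitr
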