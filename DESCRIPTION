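Package: cohesinscreen
Title: Image-Based Screening Analysis of Cohesin Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for high-content imaging screens that score
    cohesin clustering in interphase nuclei. Provides synthetic
    fluorescence-field and screen-table generators with ground truth,
    two-class Otsu nucleus segmentation, per-nucleus grayscale granulometry
    (erosion/reconstruction granularity spectra), plate-wise z-score
    normalization and multi-round siRNA hit calling, CTCF-based hit
    stratification, and DNA-FISH spot detection, greedy allele pairing and
    center-to-center distance summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
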