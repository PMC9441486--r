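Package: zonequant
Title: Zone-Resolved Compositional Analysis of Aortic Aneurysm Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for zone-resolved compositional analysis of histological
    whole-slide images of abdominal aortic aneurysm biopsies. Provides a
    synthetic-slide generator with known ground truth, tile mosaicking and
    filtering, input/target-consistent augmentation, a natively implemented
    U-Net variant with trainable Swish activations and reflection padding
    trained with a squared soft-Jaccard loss, corrected classification-report
    metrics (precision, recall, F1, Jaccard), per-class zone masks with an
    overlap quality gate, and per-zone quantification of immunopositive
    cells, DAB-stained area, and elastin/collagen fiber content via optical
    density colour deconvolution.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
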