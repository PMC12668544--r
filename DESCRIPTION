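Package: denseogm
Title: De Novo Assembly of Densely Labelled Optical DNA Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Overlap-layout-consensus assembly of densely labelled optical
    genome mapping (OGM) intensity profiles ("barcodes"). Pairwise overlaps
    are scored with a matrix-profile style maximum sliding-window Pearson
    correlation over placements, length-rescaling factors and orientations,
    together with a leftover score over the remaining mutual overlap. Scores
    are converted to p-values under a calibrated null model, combined with
    Stouffer's method, and significant overlaps are merged into barcode
    islands via a consistency-checked overlap graph. Islands are reduced to
    consensus barcodes by amplitude adjustment, column-mean drafting and
    iterative realignment. Includes a synthetic barcode simulator with
    ground truth, kymograph preprocessing utilities, and validation tools
    (ground-truth alignment tables, anchor-based island placement, true/false
    positive summaries and dot-plot data).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
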