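Package: menquant
Title: Quantification of Mitotic Exit Network Signaling from Live-Cell
    Imaging and Phosphoproteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-cell quantification toolkit for budding-yeast mitotic
    exit network (MEN) signaling. Implements FRAP double normalization and
    single-exponential recovery fitting, drift correction, marker-based
    segmentation, spindle pole body detection, backward-overlap cell
    tracking and mother-bud assignment, compartment enrichment and
    coefficient-of-variation translocation statistics, Cdc14 nucleolar
    release metrics, optogenetic recruitment slope regression,
    event-aligned ensemble averaging with confidence bands, and hit
    calling for TurboID proximity labeling and kinase-dependence
    phosphoproteomics (fold-change plus BH-FDR thresholding with
    detection-rescue rules, single-phosphopeptide-priority site calls,
    zone assignment and catalog merging). A synthetic-data module
    generates movies, FRAP traces and replicate-structured peptide tables
    with known ground truth so the full pipeline is testable without
    microscopy or mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    yaml,
    jsonlite,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
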