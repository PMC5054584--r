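Package: gestclock
Title: Gestational-Age Epigenetic Clocks from Neonatal DNA Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and applying gestational-age (GA) epigenetic
    clocks from neonatal cord-blood or blood-spot methylation arrays: quality
    control (detection-p masking, missingness filters, cross-dataset probe
    intersection), gold-standard beta-mixture quantile (BMIQ) calibration,
    k-nearest-neighbour imputation, elastic-net clock training with
    cross-validated penalty selection, DNAm-GA prediction and accuracy
    metrics, GA-acceleration association models, reference-based cell-type
    deconvolution, epigenome-wide association scans, and CpG
    island/shore/shelf enrichment tests. A synthetic-data generator emulates
    the statistical structure of neonatal methylation cohorts so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    glmnet,
    jsonlite,
    GenomicRanges,
    IRanges,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
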