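Package: cellcomm
Title: Cell-Cell Communication Networks from Sorted-Population Transcriptomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers directed ligand-receptor communication networks between
    sorted cell populations from bulk expression profiles (FPKM) and a curated
    ligand-receptor pair catalogue. Provides expression-call thresholds,
    cross-population enrichment scoring, per-population-pair interaction
    counts, receptor- and ligand-centric subnetwork extraction, and
    specificity-filtered top-N interaction ranking. A companion single-cell
    arm quantifies FACS-gate purity by clustering labelled cells and scoring
    cluster identities against marker panels. A synthetic-data module plants
    known markers, ligand-receptor senders/receivers and gate contamination
    so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
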