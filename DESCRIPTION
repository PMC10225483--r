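Package: mosaicCNA
Title: Single-Cell Copy-Number Inference and Embryo Mosaicism Concordance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers chromosome-scale copy-number alterations (CNAs) from
    low-pass single-cell whole-genome sequencing of MALBAC-amplified cells
    and from bulk CNV-seq of trophectoderm (TE) biopsies, then tests whether
    CNAs found in an infant's blood cells correspond to the mosaic CNAs
    reported in the embryo's TE biopsy. The pipeline covers variable-size
    genomic binning, depth normalization, LOWESS GC-bias correction,
    plate-pooled control correction, circular binary segmentation with a
    hybrid permutation/analytic p-value, integer copy-number calling by
    ploidy-scale optimization, cell-level quality control, a two-round
    pooled-control CNV-seq mode with mosaic-fraction estimation, and
    per-infant TE/PBMC concordance reports. A synthetic-data module
    simulates MALBAC amplification noise, mosaic cell mixtures, and
    pseudobulk biopsies so the full pipeline is testable without
    controlled-access human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
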