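Package: poisdecon
Title: Scaled-Poisson Deconvolution of Bulk RNA-seq with Single-Cell References
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Joint latent-variable modelling of bulk RNA-seq samples against a
    labelled single-cell reference under a scaled-Poisson readout model. For each
    bulk sample the model simultaneously estimates the cell-type composition, a
    per-sample scale factor, and sample-adapted cell-type-specific
    whole-transcriptome expression profiles with per-gene, per-type readout
    precisions, and partitions every observed bulk count into expected cell-type
    contributions. Also provides trimmed common-profile scale-factor estimation
    for pure samples, model-based agglomerative clustering of single-cell
    profiles with BIC model-order selection, a generative simulator for the full
    model, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    graphics,
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
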