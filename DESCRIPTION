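Package: ionflow
Title: Flow-Space Error Characterisation for Semiconductor Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Profiles the errors and biases of flowgram-based semiconductor
    sequencers (Ion Torrent PGM) directly in flow space. Provides flow-order
    arithmetic and run-length-encoded coordinate mapping, a binary SFF
    reader/writer, a generative flowgram read simulator, alignment-to-flow
    projection with per-flow over-call/under-call classification,
    high-frequency indel (HFI) site detection with strand-asymmetry testing,
    a double generalised linear model (Gaussian mean, log-linear dispersion)
    of flow-values, G+C coverage-bias regression, empirical quality-score
    recalibration and high-residual-ionogram (HRI) read trimming.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    data.table,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
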