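Package: synorth
Title: Orthologous Synteny Identification with the Orthology Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies syntenic blocks between two genomes as orthologous or
    out-paralogous using the Orthology Index, the fraction of a block's gene
    pairs that were pre-inferred as orthologs.  Provides readers for common
    collinearity formats (MCScanX, WGDI, JCVI anchors), block filtering at an
    index cutoff, syntenic-orthogroup clustering with a Markov Cluster
    implementation, synteny-depth profiling for relative-ploidy inference,
    diagnostic dot plots, and a self-contained shared-WGD gene-order simulator
    with a precision/recall benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite,
    Biostrings
Config/testthat/edition: 3
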