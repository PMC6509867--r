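Package: stagewise
Title: Stage-Specific Cancer Gene Selection and Pathway Evolution Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies stage-specific disease genes from paired gene
    expression and DNA methylation profiles by elastic-net stability
    selection over one-vs-rest tumour-stage contrasts, extracts
    stage-specific functional modules as giant connected components of the
    seed-plus-neighbour subnetwork of a protein-protein interaction network,
    performs hypergeometric pathway enrichment with Benjamini-Hochberg
    correction, and builds a pathway evolution network whose edges are
    weighted by the squared-overlap score k^2/(p*q). Includes a synthetic
    multi-omics data generator with planted stage-specific signal for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
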