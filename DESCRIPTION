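Package: mirshift
Title: Multi-Omic Nomination of miRNA Targets and Microglial Cell-State
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to nominate microRNA targets by intersecting in silico
    prediction and AGO-CLIP evidence with the most anticorrelated features
    of perturbation proteomics and per-cell-type single-cell differential
    expression; to census canonical seed-match binding sites (8mer,
    7mer-m8, 7mer-A1, 6mer) in 3'UTRs; and to analyse microglial cell
    states by binned-control signature scoring, composition-shift testing
    and pseudotime trend comparison. Ships a synthetic-data generator with
    planted ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    limma,
    jsonlite,
    fgsea,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
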