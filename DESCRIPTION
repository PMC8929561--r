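Package: psnet
Title: Protein Structure Networks with Interaction Timelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds protein structure networks whose edges carry per-frame
    interaction timelines extracted from structure ensembles (multi-model PDB
    files or MD time-series output). Scores residues for allosteric relevance
    using mutual-information measures over neighbouring interaction timelines
    (edge/node correlation factors and their two-state difference variant) and
    classical shortest-path centralities (betweenness, characteristic path
    length centrality), and benchmarks residue score tables against binary
    reference labels with ROC and precision-recall analysis. Includes seeded
    synthetic generators for coupled timelines and toy coordinate ensembles,
    readers and writers for a line-oriented interaction-timeline text format,
    and a thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
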