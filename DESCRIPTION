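Package: pdinet
Title: Analysis of Protein-DNA Interaction Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for directed transcription-factor-to-promoter (protein-DNA
    interaction) gene regulatory networks of the kind produced by enhanced
    yeast one-hybrid screens. Provides network input/output (TSV, SIF,
    GraphML), degree and hub statistics, transcription-factor family
    over-representation tests based on expected outdegree and a two-cell
    chi-square statistic, Gini-correlation-based assignment of activating or
    repressing polarity to edges from time-series expression data,
    enumeration and coherent/incoherent classification of three-node
    feed-forward loops, ortholog-based projection of networks across species
    with edge-conservation scoring, and a seeded synthetic-data generator
    (networks, expression, differential-expression tables, ortholog maps)
    with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
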