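Package: gxpr
Title: Headless Gene Expression Plotting, Clustering and Overrepresentation Analysis
Version: 0.1.0
Authors@R: person("GXP", "Maintainers", email = "gxpr@example.org", role = c("aut", "cre"))
Description: A headless analysis engine for quantitative omics tables
    (RNA-seq expression or metabolite concentrations). Parses factor-aware
    sample-name grammars from quantification tables, joins free-format
    annotation tables, aggregates replicates into expression profiles with
    error bars, renders bar/line/stacked SVG profile plots, assesses
    replicate likeness via correlation- or Euclidean-distance hierarchical
    clustering and principal component analysis, performs generic
    overrepresentation analysis with a from-scratch one-sided Fisher's
    exact test and Bonferroni or Benjamini-Hochberg correction, draws
    MapMan-style pathway sketches with per-gene colored boxes, and
    serializes whole sessions into a round-trippable zip database bundle.
    Includes a deterministic synthetic-data generator and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    grDevices,
    stats,
    utils,
    tools
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
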