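Package: fluxcsm
Title: Context-Specific Metabolic Models and Flux-Range Similarity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Builds expression-driven context-specific constraint-based
    metabolic models for two condition groups and compares them. Gene-level
    TPM tables with technical replicates are filtered, aggregated and
    discretized into expressed/unexpressed calls; a FASTCORE-family
    extraction pulls a flux-consistent subnetwork of a reference
    genome-scale model around the expressed core under a given medium;
    condition groups are then compared structurally (shared and unique
    genes, reactions and metabolites; subsystem attribution) and
    functionally, via flux variability analysis under an ATP-demand
    objective summarised per subsystem by a flux-range similarity index.
    Includes a synthetic network and expression generator with planted
    silenced subsystems, so the whole pipeline is testable end to end, and
    a bounded-variable simplex solver for the underlying linear programs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    mclust,
    methods,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
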