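Package: feaspath
Title: Feasible Metabolic Pathway Inference from Transcriptome and
    Phenotype Microarray Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates genome annotation, expression microarray and
    Biolog phenotype-microarray (PM) data to infer which metabolic
    pathways are feasible in a bacterium under a reference growth
    condition, in the style of systems studies of Mycobacterium
    smegmatis. Provides percentile-based normalization of log-scale
    array intensities, coverage-based pathway feasibility
    classification with paralog (duplicate-gene) resolution,
    bidirectional best-hit annotation transfer between proteomes,
    discretization and hierarchical clustering of PM respiration
    kinetics, rule-based prediction of nutrient utilization from
    transporter and enzyme evidence, and a synthetic-data module that
    generates all fixtures with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
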