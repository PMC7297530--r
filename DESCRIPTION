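Package: apicalmap
Title: Quantitative Synaptic Input Mapping of Pyramidal-Cell Apical Dendrites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative connectomic analysis of synaptic
    innervation of cortical pyramidal-cell apical dendrites from skeleton
    annotations. Reads and writes webKnossos-style NML skeleton files,
    measures dendritic morphometry (shaft path length, diameter, surface
    area, main-bifurcation landmarks), classifies input synapses into
    excitatory and putative-inhibitory classes, computes per-dendrite
    densities and inhibitory fractions with axon-identity correction,
    analyses axonal target preference with bootstrap specificity tests,
    classifies layer-5 pyramidal subtypes by hierarchical clustering and
    principal components, fits distance-dependence models (exponential with
    offset, linear, linear-fraction), and ships a synthetic annotation
    generator with ground truth for every recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    xml2,
    igraph,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'skeleton-io.R'
    'morphometry.R'
    'synapse-quant.R'
    'axon-analysis.R'
    'celltype-models.R'
    'synthetic-data.R'
    'pipeline.R'
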