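Package: netKM
Title: Network-Structured Kernel Machine Tests for Module-Based
    Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Kernel machine regression for testing the joint effect of
    modules of bio-elements (metabolites, genes, SNPs) on a continuous
    trait, with kernels that incorporate the module's network structure.
    Provides the topological overlap matrix, topology and connectivity
    kernels, the Hadamard interaction kernel, REML/EM variance-component
    fitting, score tests for module-module interaction and conditional
    module effects with moment-matched weighted chi-squared p-values, and
    a simulation engine for type-I error and power studies on scale-free
    and non-scale-free module structures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'network.R'
    'kernels.R'
    'reml.R'
    'scoreTest.R'
    'simulate.R'
    'io.R'
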