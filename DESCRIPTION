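Package: armae
Title: Simulation and Quantification of Autosomal Random Monoallelic
    Expression from Dual-Reporter Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying autosomal random monoallelic expression
    (aRMAE) in clonal tissues with two-colour reporter alleles, modelled on
    the Caenorhabditis elegans intestine.  Provides a generative simulator
    for clonal allele silencing on the fixed 20-cell E lineage, a synthetic
    two-channel confocal stack renderer with nucleus segmentation and
    quantification, per-experiment normalization, per-cell intrinsic-noise
    and allele-bias (R squared) statistics, monoallelic state calling with
    parsimony-based inference of the lineage division at which silencing
    initiated, and the nonparametric test battery (Mann-Whitney,
    Kruskal-Wallis, Dunn's procedure) used to compare genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    readxl,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
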