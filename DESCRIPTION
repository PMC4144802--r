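Package: plastdiff
Title: Pairwise Comparative Analysis of Plastid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for fine-scale comparison of two conspecific chloroplast
    (plastid) genomes. Detects the quadripartite LSC/SSC/IR architecture,
    aligns homologous regions with an anchored affine-gap aligner, calls and
    classifies indels (homopolymer slippage, tandem-repeat, other; carrier
    and outgroup-polarized orientation) and SNPs (compartment, transition/
    transversion, synonymous/nonsynonymous under the plastid genetic code),
    and summarizes per-region variant densities, Ts/Tv ratios and Kimura
    two-parameter distances. Characterizes tandem arrays of short palindromic
    repeat units in hypervariable intergenic spacers: unit detection,
    stem-loop hairpin folding, per-position consensus profiles and dot-plot
    matrices. Computes pairwise-deletion p-distance matrices, group mean
    distances, fold differences and calibration-ratio divergence-time
    estimates. Includes a seeded synthetic plastome-pair generator with a
    machine-readable truth catalog so the whole pipeline can be validated
    offline against planted mutation events.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    vcfR,
    withr,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
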