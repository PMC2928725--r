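Package: epiqtl
Title: Power and Model Selection for Epistatic QTL in Association Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how molecular epistasis between two
    quantitative trait loci affects detection power and model selection in
    population-based association scans. Provides constrained two-locus
    genotypic-means models (additive plus five masking/epistasis patterns)
    with a fixed phenotypic range, exact expected sums of squares and
    noncentral-F analytic power for the balanced cell-means ANOVA, a
    coalescent-with-recombination simulator of SNP panels with
    allele-frequency-conditioned QTL mutations, phenotype generation, a
    two-step BIC model-selection genome scan over phylogenetically
    compatible marker blocks, and replicated-experiment summaries of power,
    selection accuracy and false discovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
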