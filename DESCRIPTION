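Package: beanABC
Title: Coalescent Simulation and Approximate Bayesian Computation for
    Wild Common Bean Demography
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Demographic inference for the three wild gene pools of common
    bean (Mesoamerican, southern Andean, and Northern Peru-Ecuador) by
    structured coalescent simulation with founder bottlenecks, SNP summary
    statistics (nucleotide diversity, Tajima's D, Weir-Cockerham Fst,
    haplotype-block N50), and approximate Bayesian computation: model
    choice via rejection, multinomial logistic regression and neural
    network classifiers with Bayes factors, parameter posteriors with
    confidence and highest-posterior-density intervals, and rejection
    cross-validation.  Includes VCF/GFF/BED input with the standard
    genotype filter chain, neutral-site classification, and a synthetic
    data generator so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
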