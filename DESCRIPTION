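Package: RareVarPower
Title: Empirical Power Benchmarking of Rare-Variant Association Tests
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation framework for benchmarking gene-based rare-variant
    association methods on calibrated synthetic sequence panels. Generates
    genotype panels whose minor-allele-frequency spectra, singleton fractions
    and rare-variant carrier distributions match printed per-gene summaries
    from a large Sanger-sequenced cohort (n = 1,998, seven genes); simulates
    continuous and extreme-sampled dichotomous phenotypes under six control
    scenarios and a systematic effect-size by causal-fraction grid; and
    estimates empirical power for single-marker regression and seven
    gene-level tests (T1, T5, WE, VT, WOD1, WOD5, SKAT), all calibrated by
    phenotype permutation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, StatisticalMethod, GeneticVariability, Genetics,
    VariantAnnotation
RoxygenNote: 7.3.3
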