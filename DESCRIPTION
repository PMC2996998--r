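Package: eqtlbench
Title: Multi-Locus eQTL Mapping with Bias-Corrected Random Forest
    Selection Frequency and Knowledge-Driven Benchmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps expression quantitative trait loci (eQTL) in recombinant
    inbred panels with single-marker regression (Haley-Knott LOD), a
    simplified marker-based composite interval mapping, lasso and elastic
    net coefficient scoring, and Random Forest variable importances,
    including a bias-corrected selection frequency (RFSF) that removes the
    under-selection of markers in linkage disequilibrium by subtracting
    per-marker deviations of the null selection frequency from its mean.
    Ships a simulation engine for additive and epistatic trait models on
    synthetic recombinant inbred genotypes, and a battery of knowledge-driven
    benchmarks: cis-eQTL proportion, hypergeometric pathway enrichment with
    an empirical-null correction and Kolmogorov-Smirnov summaries, mutant
    loss-of-function enrichment, and between-method overlap of top-scoring
    loci.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
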