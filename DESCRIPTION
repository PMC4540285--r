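Package: snpbench
Title: Benchmarking SNP Encodings and Classifiers for Disease Risk Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for benchmarking machine-learning models of
    disease risk from genome-wide SNP genotype data. Provides simulation of
    case-control cohorts under Hardy-Weinberg equilibrium with configurable
    causal architectures, PLINK text PED/MAP input and output, marker quality
    control (minor allele frequency, call rate, Hardy-Weinberg equilibrium),
    the five single-marker association tests used for per-fold feature
    selection (allelic, dominant, recessive, genotypic and Cochran-Armitage
    trend), three genotype feature encodings (additive, recessive/dominant,
    genotypic) with training-fold standardization, nested 5x2 cross-validated
    evaluation of seven classifier families by AUC, and a rank-based
    inference layer (Friedman and Iman-Davenport omnibus tests, pairwise z
    tests with Nemenyi and Shaffer static corrections, critical-distance
    grouping) for comparing treatments across many benchmark problems.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    ranger,
    rpart,
    nnet
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
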