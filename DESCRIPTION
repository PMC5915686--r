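Package: gxgtools
Title: Multifactorial Gene-Gene Interaction Analysis for Case-Control SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for candidate-gene case-control studies of
    biallelic SNP panels: single-locus association statistics (allelic,
    genotypic, dominant and recessive odds ratios with Woolf confidence
    intervals, chi-square and Fisher tests, Bonferroni correction, power),
    multifactor dimensionality reduction (MDR) with cross-validated balanced
    accuracy, cross-validation consistency and permutation testing,
    classification-and-regression-tree risk partitioning over genotypes with
    cost-complexity pruning and terminal-node odds ratios, unweighted genetic
    risk scores with binned risk analysis, and a synthetic genotype simulator
    (Hardy-Weinberg populations, marginal per-allele odds ratios, multi-locus
    penetrance models including purely epistatic ones, and marginal-matched
    reconstruction from published genotype-count tables).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rpart,
    vcfR,
    readxl
Config/testthat/edition: 3
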